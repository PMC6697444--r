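#' Stratify a gene universe by binding-element class
#'
#' Scans each gene's sequence for compact and extended binding elements
#' (sense strand only) and returns gene-id sets for the four strata used
#' in motif-stratified enrichment: genes matching a compact element, genes
#' matching an extended element, genes matching either, and genes matching
#' compact but not extended.
#'
#' @param genes Tibble with columns `gene_id` (unique) and `seq`.
#' @param patterns Pattern tibble (default [puf_patterns()]); rows with
#'   `element_class == "compact"` / `"extended"` define the two classes.
#' @return Named list of character vectors: `compact`, `extended`,
#'   `either`, `compact_only`.
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", seq = "AACTGTGAATCC")
#' stratify_targets(genes)
#' @export
stratify_targets <- function(genes, patterns = puf_patterns()) {
  if (nrow(genes) == 0L) stop("gene universe must be nonempty", call. = FALSE)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in universe", call. = FALSE)
  }
  match_class <- function(class) {
    pats <- patterns$pattern[patterns$element_class == class]
    hit <- rep(FALSE, nrow(genes))
    for (p in pats) hit <- hit | match_pattern(genes$seq, p)
    genes$gene_id[hit]
  }
  compact <- match_class("compact")
  extended <- match_class("extended")
  list(
    compact = compact,
    extended = extended,
    either = union(compact, extended),
    compact_only = setdiff(compact, extended)
  )
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate correction:
#' `q_(i) = min over j >= i of m * p_(j) / j`, clipped at 1 and mapped
#' back to the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric term enrichment over a target gene set
#'
#' For each term, tests whether genes annotated to the term are
#' over-represented in the target set relative to the universe with an
#' upper-tail hypergeometric test (`p = P(X >= k)` under
#' `Hypergeometric(N, K, n)`), then applies Benjamini-Hochberg correction
#' across all tested terms. Terms with no annotated genes in the universe
#' are skipped with a warning. One-sided (enrichment only).
#'
#' @param target Character vector of target gene ids (must be a subset of
#'   the universe).
#' @param genes Universe tibble with a `gene_id` column.
#' @param annotations Tibble with columns `gene_id`, `term`.
#' @return Tibble sorted by p-value with columns `term`, `k` (annotated
#'   in target), `K` (annotated in universe), `n` (target size), `N`
#'   (universe size), `p_value`, `q_value`.
#' @examples
#' genes <- tibble::tibble(gene_id = sprintf("g%d", 1:10))
#' ann <- tibble::tibble(gene_id = sprintf("g%d", 1:5), term = "T")
#' hypergeom_enrich(sprintf("g%d", 1:3), genes, ann)
#' @export
hypergeom_enrich <- function(target, genes, annotations) {
  universe <- genes$gene_id
  if (!all(target %in% universe)) {
    stop("target gene ids must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(target)
  terms <- unique(annotations$term)
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]

  res <- purrr::map_dfr(terms, function(tm) {
    term_genes <- unique(ann$gene_id[ann$term == tm])
    K <- length(term_genes)
    if (K == 0L) {
      warning("term '", tm, "' has no annotated genes in the universe; skipped",
              call. = FALSE)
      return(NULL)
    }
    k <- length(intersect(term_genes, target))
    # upper tail P(X >= k)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term = tm, k = k, K = K, n = n, N = N, p_value = p)
  })
  if (nrow(res) == 0L) return(res)
  res$q_value <- bh_adjust(res$p_value)
  dplyr::arrange(res, .data$p_value)
}

#' Motif-stratified enrichment in one call
#'
#' Stratifies the universe with [stratify_targets()] and runs
#' [hypergeom_enrich()] on the chosen stratum.
#'
#' @inheritParams hypergeom_enrich
#' @inheritParams stratify_targets
#' @param stratum One of `"compact"`, `"extended"`, `"either"`,
#'   `"compact_only"`.
#' @return An enrichment tibble (see [hypergeom_enrich()]).
#' @export
enrich_by_element <- function(genes, annotations,
                              stratum = c("compact_only", "compact",
                                          "extended", "either"),
                              patterns = puf_patterns()) {
  stratum <- match.arg(stratum)
  sets <- stratify_targets(genes, patterns)
  hypergeom_enrich(sets[[stratum]], genes, annotations)
}
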