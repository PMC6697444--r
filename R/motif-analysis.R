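#' Count element-pattern matches in a read set
#'
#' Counts, for each pattern, the number of reads containing at least one
#' match (grep line semantics: a read contributes at most one count per
#' pattern, and a read matching several patterns increments each of them
#' independently). An occurrence-level mode counts every matching window
#' instead.
#'
#' @param reads Read tibble (columns `read_id`, `seq`) or character vector
#'   of sequences.
#' @param patterns Pattern tibble as from [puf_patterns()].
#' @param dataset_label Label recorded in the output (e.g. `"FBF-2"`).
#' @param mode `"reads"` (default; presence/absence per read) or
#'   `"occurrences"` (total matching windows).
#' @param dedup If `TRUE`, duplicate sequences are collapsed before
#'   counting.
#' @return A tibble with columns `dataset`, `name`, `pattern`,
#'   `element_class`, `base4`, `terminal_au`, `count`.
#' @examples
#' reads <- simulate_library(100, seed = 1)
#' count_patterns(reads, puf_patterns(), "demo")
#' @export
count_patterns <- function(reads, patterns = puf_patterns(),
                           dataset_label = "dataset",
                           mode = c("reads", "occurrences"),
                           dedup = FALSE) {
  mode <- match.arg(mode)
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (length(seqs) == 0L) stop("reads must be nonempty", call. = FALSE)
  if (nrow(patterns) == 0L) stop("pattern list must be nonempty", call. = FALSE)
  if (dedup) seqs <- unique(seqs)
  counts <- vapply(patterns$pattern, function(p) {
    occ <- count_occurrences(seqs, p)
    if (mode == "reads") sum(occ > 0L) else sum(occ)
  }, integer(1))
  dplyr::mutate(patterns,
                dataset = dataset_label,
                count = unname(counts),
                .before = 1)
}

#' Compact:extended count ratio at a given +4 base
#'
#' The ratio of compact-element to extended-element read counts for one
#' dataset and one +4 base identity. A ratio above 1 means the +4 base is
#' preferentially found in the shorter (1:1 register) element; below 1,
#' in the extended element with flipped central bases.
#'
#' @param count_table Output of [count_patterns()] (rows for one or more
#'   datasets), or any tibble with columns `dataset`, `element_class`,
#'   `base4`, `count`.
#' @param dataset_label Dataset to extract.
#' @param base4 `"A"`, `"G"` or `"R"`.
#' @return The unrounded ratio `compact_count / extended_count`. Reporting
#'   helpers round to 2 significant figures.
#' @examples
#' tbl <- tibble::tibble(dataset = "x", element_class = c("compact", "extended"),
#'                       base4 = "A", count = c(10L, 40L))
#' compact_extended_ratio(tbl, "x", "A")
#' @export
compact_extended_ratio <- function(count_table, dataset_label, base4) {
  rows <- count_table[count_table$dataset == dataset_label &
                        count_table$base4 == base4, , drop = FALSE]
  compact <- rows$count[rows$element_class == "compact"]
  extended <- rows$count[rows$element_class == "extended"]
  if (length(compact) != 1L || length(extended) != 1L) {
    stop("need exactly one compact and one extended count for (",
         dataset_label, ", ", base4, ")", call. = FALSE)
  }
  if (extended == 0L) {
    stop("ratio undefined: extended count is 0 for (", dataset_label,
         ", ", base4, ")", call. = FALSE)
  }
  compact / extended
}

#' Summarise a count table with per-+4-base ratios
#'
#' Reshapes a [count_patterns()] table into one row per (dataset, +4 base)
#' with compact and extended counts side by side and the compact:extended
#' ratio (`NA` where the extended count is zero). Ratios are reported
#' unrounded; use `signif(ratio, 2)` for display at the conventional
#' 2-significant-figure precision.
#'
#' @param count_table Output of [count_patterns()], possibly for several
#'   datasets.
#' @return A tibble with columns `dataset`, `base4`, `compact_count`,
#'   `extended_count`, `ratio`.
#' @export
ratio_table <- function(count_table) {
  wide <- count_table |>
    dplyr::select(dplyr::all_of(c("dataset", "base4", "element_class",
                                  "count"))) |>
    tidyr::pivot_wider(names_from = "element_class",
                       values_from = "count",
                       names_glue = "{element_class}_count")
  dplyr::mutate(
    wide,
    ratio = ifelse(.data$extended_count > 0,
                   .data$compact_count / .data$extended_count, NA_real_)
  )
}

#' Build a position frequency matrix around matched elements
#'
#' Aligns reads on their first match to an anchor pattern and tabulates
#' base frequencies over a window in motif coordinates (the first U of the
#' UGU anchor is +1, the upstream C is -1; there is no position 0). Reads
#' whose window extends past either end are dropped. A stand-in for
#' EM-based motif discovery: the anchor defines the alignment, the matrix
#' summarises the flanking preferences.
#'
#' @param reads Read tibble or character vector.
#' @param anchor_pattern Pattern string used to anchor the alignment
#'   (default the generic compact element).
#' @param window Integer vector of length 2: first and last motif position
#'   (default `c(-2, 9)`).
#' @param pseudocount Added to every cell before normalising (default 0).
#' @return An object of class `puf_pfm`: list with `prob` (4 x positions
#'   matrix), `ic` (bits per position), `n_sites`, `window`.
#' @export
build_pfm <- function(reads, anchor_pattern = "CTGTRNAT",
                      window = c(-2L, 9L), pseudocount = 0) {
  seqs <- normalize_seq(if (is.data.frame(reads)) reads$seq else reads)
  .check_read_alphabet(seqs)
  stopifnot(length(window) == 2L, window[1] < window[2], pseudocount >= 0)

  anchor <- chartr(".", "N", normalize_seq(anchor_pattern))
  subject <- Biostrings::DNAStringSet(seqs)
  hits <- Biostrings::vmatchPattern(Biostrings::DNAString(anchor), subject,
                                    fixed = "subject")
  first <- vapply(Biostrings::startIndex(hits), function(s) {
    if (is.null(s) || length(s) == 0L) NA_integer_ else s[[1]]
  }, integer(1))

  # motif positions skip 0: -1 is the C at the anchor start
  positions <- setdiff(seq(window[1], window[2]), 0L)
  # string index of motif position p when the anchor's C sits at `first`
  pos_index <- function(p, start) start + p + ifelse(p < 0, 1L, 0L)

  lo <- pos_index(positions[1], first)
  hi <- pos_index(positions[length(positions)], first)
  keep <- !is.na(first) & lo >= 1L & hi <= nchar(seqs)
  if (!any(keep)) {
    stop("no reads contain the anchor with the full window in range",
         call. = FALSE)
  }
  seqs <- seqs[keep]
  first <- first[keep]

  bases <- c("A", "C", "G", "T")
  counts <- sapply(positions, function(p) {
    idx <- pos_index(p, first)
    tab <- table(factor(substr(seqs, idx, idx), levels = bases))
    as.numeric(tab)
  })
  rownames(counts) <- bases
  colnames(counts) <- ifelse(positions > 0, paste0("+", positions),
                             as.character(positions))
  counts <- counts + pseudocount
  prob <- sweep(counts, 2, colSums(counts), "/")
  ic <- apply(prob, 2, function(p) {
    2 + sum(ifelse(p > 0, p * log2(p), 0))
  })
  structure(list(prob = prob, ic = ic, n_sites = sum(keep),
                 window = window),
            class = "puf_pfm")
}

#' @export
print.puf_pfm <- function(x, ...) {
  cat("Position frequency matrix (", x$n_sites, " aligned sites, window ",
      x$window[1], "..", "+", x$window[2], ")\n", sep = "")
  print(round(x$prob, 3))
  cat("Information content (bits):\n")
  print(round(x$ic, 3))
  invisible(x)
}

#' @rdname build_pfm
#' @param x A `puf_pfm` object.
#' @export
tidy.puf_pfm <- function(x, ...) {
  tibble::as_tibble(as.table(x$prob), .name_repair = ~ c("base", "position",
                                                         "prob")) |>
    dplyr::left_join(
      tibble::tibble(position = names(x$ic), ic = unname(x$ic)),
      by = "position"
    )
}
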