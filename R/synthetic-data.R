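#' Simulate a random-core selection library
#'
#' Generates the round-0 RNA library of an in vitro selection (SEQRS)
#' experiment: a fixed 5' flank, a random core with i.i.d. uniform bases,
#' and a fixed 3' flank. Sequences are stored as DNA (U mapped to T).
#'
#' @param n_reads Number of reads to generate.
#' @param core_length Length of the random core (default 20 nt, the depth
#'   of the starting dsDNA pool).
#' @param flank_5p,flank_3p Fixed flanking sequences (may be empty).
#' @param seed Integer seed; the same seed reproduces the library exactly.
#' @return A tibble with columns `read_id` and `seq`.
#' @examples
#' simulate_library(5, seed = 1)
#' @export
simulate_library <- function(n_reads, core_length = 20L,
                             flank_5p = "", flank_3p = "", seed) {
  stopifnot(n_reads >= 0, core_length > 0)
  flank_5p <- normalize_seq(flank_5p)
  flank_3p <- normalize_seq(flank_3p)
  if (grepl("[^ACGT]", flank_5p) || grepl("[^ACGT]", flank_3p)) {
    stop("flanks must be over {A,C,G,T,U}", call. = FALSE)
  }
  if (n_reads == 0L) {
    return(tibble::tibble(read_id = character(0), seq = character(0)))
  }
  cores <- withr::with_seed(seed, {
    mat <- matrix(sample(c("A", "C", "G", "T"), n_reads * core_length,
                         replace = TRUE),
                  nrow = n_reads)
    apply(mat, 1, paste0, collapse = "")
  })
  tibble::tibble(
    read_id = sprintf("read_%d", seq_len(n_reads)),
    seq     = paste0(flank_5p, cores, flank_3p)
  )
}

#' Selection model for affinity-driven round-to-round enrichment
#'
#' Bundles the parameters of the retention model used by
#' [simulate_selection()]. Each read is retained with weight
#' `w = theta + b`, where `theta = P / (P + Kd)` is the equilibrium
#' fractional occupancy of the read's tightest matching element class
#' (`theta = 0` for non-matching reads) and `b` is a class-independent
#' background retention probability (carrier tRNA and plastic binding
#' retain non-binders regardless of protein occupancy).
#'
#' Default class dissociation constants are the measured affinities of the
#' corresponding elements: compact G4 10.3 nM (cFBE), compact A4 56.8 nM
#' (PBE), extended G4 12.4 nM (gld-1 FBEa) and extended A4 12.0 nM
#' (gld-1 G4A).
#'
#' @param protein_concentration Free protein concentration in nM.
#' @param class_kd Named numeric vector mapping element-class labels (the
#'   `name` column of the pattern set) to dissociation constants in nM.
#' @param background_retention Probability in `[0, 1]` that a non-binding
#'   read survives a round.
#' @param rounds Number of selection rounds (>= 1; the study design uses 5).
#' @param reads_per_round Reads resampled into each round.
#' @return A list of class `selection_model`.
#' @export
selection_model <- function(protein_concentration = 100,
                            class_kd = c(compact_G4 = 10.3,
                                         compact_A4 = 56.8,
                                         extended_G4 = 12.4,
                                         extended_A4 = 12.0),
                            background_retention = 0.01,
                            rounds = 5L,
                            reads_per_round = 1e5L) {
  stopifnot(protein_concentration >= 0,
            all(class_kd > 0),
            background_retention >= 0, background_retention <= 1,
            rounds >= 1, reads_per_round >= 1)
  if (is.null(names(class_kd)) || any(!nzchar(names(class_kd)))) {
    stop("class_kd must be a named vector of element-class labels",
         call. = FALSE)
  }
  structure(
    list(protein_concentration = protein_concentration,
         class_kd = class_kd,
         background_retention = background_retention,
         rounds = as.integer(rounds),
         reads_per_round = as.integer(reads_per_round)),
    class = "selection_model"
  )
}

# Occupancy-plus-background retention weight for each read, given the
# lowest Kd among its matching classes (NA for non-matching reads).
.retention_weights <- function(best_kd, model) {
  theta <- ifelse(is.na(best_kd), 0,
                  model$protein_concentration /
                    (model$protein_concentration + best_kd))
  theta + model$background_retention
}

# Lowest Kd among matching element classes, per unique sequence.
.best_kd <- function(seqs, patterns, class_kd) {
  missing <- setdiff(patterns$name, names(class_kd))
  if (length(missing) > 0L) {
    stop("pattern classes missing from class_kd: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  best <- rep(NA_real_, length(seqs))
  for (i in seq_len(nrow(patterns))) {
    hit <- match_pattern(seqs, patterns$pattern[i])
    kd <- class_kd[[patterns$name[i]]]
    best[hit] <- pmin(best[hit], kd, na.rm = TRUE)
  }
  best
}

#' Simulate rounds of affinity-driven selection
#'
#' Runs the retention model of [selection_model()] over the requested
#' number of rounds. Each round assigns every read a weight
#' `w = theta + b` (occupancy of its tightest matching class plus
#' background) and draws the next round as a multinomial resample of
#' `reads_per_round` reads with probabilities `w / sum(w)`. PCR
#' amplification is modelled as neutral (resampling only).
#'
#' @param library A read tibble from [simulate_library()] (columns
#'   `read_id`, `seq`).
#' @param model A [selection_model()].
#' @param patterns Pattern tibble as from [puf_patterns()]; class labels
#'   (`name`) must all appear in `model$class_kd`. By default, the
#'   built-in patterns named in `model$class_kd`.
#' @param seed Integer seed for the resampling.
#' @return A list of read tibbles, one per round (`round_1` ... `round_k`).
#' @export
simulate_selection <- function(library, model, patterns = NULL, seed) {
  if (nrow(library) == 0L) stop("library must be nonempty", call. = FALSE)
  stopifnot(inherits(model, "selection_model"))
  if (is.null(patterns)) {
    builtin <- puf_patterns()
    patterns <- builtin[builtin$name %in% names(model$class_kd), , drop = FALSE]
    if (nrow(patterns) == 0L) {
      stop("no built-in patterns match the class_kd labels; pass `patterns`",
           call. = FALSE)
    }
  }

  # weights depend only on the sequence; compute once per unique sequence
  uniq <- unique(library$seq)
  best_kd <- .best_kd(uniq, patterns, model$class_kd)
  w_uniq <- .retention_weights(best_kd, model)
  names(w_uniq) <- uniq

  rounds <- vector("list", model$rounds)
  current <- library$seq
  withr::with_seed(seed, {
    for (k in seq_len(model$rounds)) {
      w <- w_uniq[current]
      if (sum(w) <= 0) stop("all retention weights are zero", call. = FALSE)
      idx <- sample.int(length(current), size = model$reads_per_round,
                        replace = TRUE, prob = w)
      current <- current[idx]
      rounds[[k]] <- tibble::tibble(
        read_id = sprintf("round%d_read_%d", k, seq_along(current)),
        seq     = current
      )
    }
  })
  names(rounds) <- sprintf("round_%d", seq_len(model$rounds))
  rounds
}

#' Simulate replicate EMSA titrations
#'
#' Generates noisy bound-signal measurements over a protein concentration
#' series under the one-site specific binding model
#' `Y = Bmax * X / (Kd + X)` with additive Gaussian noise truncated at
#' zero. The default concentration series is the standard two-fold EMSA
#' dilution from 4000 nM down to 0.49 nM plus a zero point.
#'
#' @param true_kd True dissociation constant in nM.
#' @param bmax Saturating signal.
#' @param concentrations Protein concentration series in nM (must contain
#'   0 and be nonnegative).
#' @param noise_sd Noise standard deviation as a fraction of `bmax`
#'   (>= 0).
#' @param n_replicates Number of technical replicates.
#' @param seed Integer seed.
#' @return A tibble with columns `replicate_id`, `concentration_nM`,
#'   `signal`.
#' @examples
#' simulate_titration(true_kd = 10, noise_sd = 0, n_replicates = 1, seed = 1)
#' @export
simulate_titration <- function(true_kd, bmax = 1,
                               concentrations = emsa_concentration_series(),
                               noise_sd = 0.05, n_replicates = 3L, seed) {
  stopifnot(true_kd > 0, bmax > 0, n_replicates >= 1)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(concentrations < 0) || !any(concentrations == 0)) {
    stop("concentrations must be nonnegative and contain 0", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    replicate_id = sprintf("rep_%d", seq_len(n_replicates)),
    concentration_nM = concentrations
  )
  mu <- bmax * grid$concentration_nM / (true_kd + grid$concentration_nM)
  eps <- withr::with_seed(seed, stats::rnorm(nrow(grid), 0, noise_sd * bmax))
  grid$signal <- pmax(mu + eps, 0)
  grid
}

#' Standard EMSA protein concentration series
#'
#' The two-fold dilution series used in the gel-shift titrations: 4000 nM
#' halved down to 0.49 nM, plus a protein-free point.
#'
#' @return Numeric vector of 15 concentrations in nM, descending.
#' @export
emsa_concentration_series <- function() {
  c(4000, 2000, 1000, 500, 250, 125, 62.5, 31.2, 15.6, 7.8, 3.9, 1.95,
    0.98, 0.49, 0)
}

#' Generate gene/term fixtures with planted binding elements
#'
#' Builds a synthetic gene universe for enrichment testing: random
#' UTR-like sequences, term annotations assigned at a fixed rate, and, for
#' terms listed in `planted`, an embedded element of the stated class at a
#' random position in every annotated gene.
#'
#' @param n_genes Number of genes (> 0).
#' @param terms Character vector of term labels.
#' @param planted Named list/character vector mapping a term label to an
#'   element-class pattern name from `patterns` (e.g.
#'   `c(term_A = "compact_G4")`). Every gene annotated to that term gets a
#'   concrete instance of the class pattern planted at a random position.
#' @param utr_length Length of each random sequence (default 200 nt).
#' @param annotation_rate Probability that a gene is annotated to each
#'   term, independently (default 0.1).
#' @param patterns Pattern tibble used to realise planted elements.
#' @param seed Integer seed.
#' @return A list with `genes` (tibble `gene_id`, `seq`) and `annotations`
#'   (tibble `gene_id`, `term`).
#' @export
generate_gene_fixtures <- function(n_genes, terms = character(0),
                                   planted = character(0),
                                   utr_length = 200L,
                                   annotation_rate = 0.1,
                                   patterns = puf_patterns(), seed) {
  stopifnot(n_genes > 0, utr_length > 0)
  planted <- unlist(planted)
  if (length(planted) > 0L) {
    if (is.null(names(planted)) || !all(names(planted) %in% terms)) {
      stop("planted terms must be named and listed in `terms`",
           call. = FALSE)
    }
    if (!all(planted %in% patterns$name)) {
      stop("planted element classes must be pattern names", call. = FALSE)
    }
  }
  withr::with_seed(seed, {
    mat <- matrix(sample(c("A", "C", "G", "T"), n_genes * utr_length,
                         replace = TRUE),
                  nrow = n_genes)
    seqs <- apply(mat, 1, paste0, collapse = "")
    gene_ids <- sprintf("gene_%d", seq_len(n_genes))

    ann <- tidyr::expand_grid(gene_id = gene_ids, term = terms)
    if (nrow(ann) > 0L) {
      ann <- ann[stats::runif(nrow(ann)) < annotation_rate, , drop = FALSE]
    }

    for (term in names(planted)) {
      pat <- patterns$pattern[patterns$name == planted[[term]]]
      for (gid in ann$gene_id[ann$term == term]) {
        i <- match(gid, gene_ids)
        inst <- .realize_pattern(pat)
        pos <- sample.int(utr_length - nchar(inst) + 1L, 1L)
        substr(seqs[i], pos, pos + nchar(inst) - 1L) <- inst
      }
    }
    list(
      genes = tibble::tibble(gene_id = gene_ids, seq = seqs),
      annotations = tibble::as_tibble(ann)
    )
  })
}

# Draw a concrete sequence matching a degenerate pattern (R -> A/G,
# N -> any base), used to plant elements in fixtures.
.realize_pattern <- function(pattern) {
  chars <- strsplit(normalize_seq(pattern), "")[[1]]
  paste0(vapply(chars, function(ch) {
    choices <- .pattern_alphabet[[ch]]
    if (is.null(choices)) stop("bad pattern character: ", ch, call. = FALSE)
    if (length(choices) == 1L) choices else sample(choices, 1L)
  }, character(1)), collapse = "")
}
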