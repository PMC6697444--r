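# Independent oracles, deliberately naive: these re-derive expectations
# without touching the production code paths they check.

# character-set table for degenerate pattern symbols
oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), N = c("A", "C", "G", "T"), `.` = c("A", "C", "G", "T")
)

# sliding-window matcher: does `read` contain a window matching `pattern`?
oracle_match <- function(read, pattern) {
  read <- chartr("U", "T", toupper(read))
  pattern <- chartr("U", "T", toupper(pattern))
  pc <- strsplit(pattern, "")[[1]]
  rc <- strsplit(read, "")[[1]]
  L <- length(pc)
  if (length(rc) < L) return(FALSE)
  for (s in seq_len(length(rc) - L + 1L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(rc[s + j - 1L] %in% oracle_sets[[pc[j]]])) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

oracle_count_reads <- function(reads, pattern) {
  sum(vapply(reads, oracle_match, logical(1), pattern = pattern))
}

# dense grid search for the one-site model, refined once around the optimum
oracle_grid_kd <- function(x, y, kd_range = c(0.1, 4000),
                           bmax_range = NULL, n_grid = 120) {
  if (is.null(bmax_range)) bmax_range <- c(max(y) / 4, max(y) * 2)
  sse <- function(kd, bmax) sum((y - bmax * x / (kd + x))^2)
  best <- c(NA, NA, Inf)
  for (pass in 1:3) {
    kds <- exp(seq(log(kd_range[1]), log(kd_range[2]), length.out = n_grid))
    bms <- seq(bmax_range[1], bmax_range[2], length.out = n_grid)
    vals <- outer(kds, bms, Vectorize(sse))
    i <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best <- c(kds[i[1]], bms[i[2]], vals[i[1], i[2]])
    kd_range <- c(best[1] / 1.5, best[1] * 1.5)
    bmax_range <- c(best[2] * 0.8, best[2] * 1.2)
  }
  list(kd = best[1], bmax = best[2], sse = best[3])
}

# exhaustive hypergeometric upper tail P(X >= k): enumerate all C(N, n)
# target draws for small N
oracle_hyper_tail <- function(k, K, N, n) {
  ids <- seq_len(N)
  annotated <- seq_len(K)
  draws <- utils::combn(ids, n)
  hits <- apply(draws, 2, function(d) sum(d %in% annotated))
  mean(hits >= k)
}

# BH step-up by the textbook formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

random_reads <- function(n, len, seed) {
  withr::with_seed(seed, {
    apply(matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
                 nrow = n), 1, paste0, collapse = "")
  })
}

# window-vectorised variant of the sliding-window matcher: same logic,
# one vectorised character test per (window, position) instead of
# per-read loops, for the large-scale equivalence check
oracle_count_reads_vec <- function(reads, pattern) {
  reads <- chartr("U", "T", toupper(reads))
  pc <- strsplit(chartr("U", "T", toupper(pattern)), "")[[1]]
  L <- length(pc)
  len <- nchar(reads)
  hit <- rep(FALSE, length(reads))
  for (s in seq_len(max(len) - L + 1L)) {
    ok <- (len >= s + L - 1L) & !hit
    if (!any(ok)) next
    w <- rep(FALSE, length(reads))
    w[ok] <- TRUE
    for (j in seq_len(L)) {
      idx <- which(w)
      if (length(idx) == 0L) break
      ch <- substr(reads[idx], s + j - 1L, s + j - 1L)
      w[idx] <- ch %in% oracle_sets[[pc[j]]]
    }
    hit <- hit | w
  }
  sum(hit)
}
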