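test_that("simulated libraries have uniform cores and fixed flanks", {
  lib <- simulate_library(1e5, core_length = 20, seed = 42)
  expect_equal(nrow(lib), 1e5)
  expect_true(all(nchar(lib$seq) == 20))
  # per-position base frequencies within 3 SE of 1/4
  se <- sqrt(0.25 * 0.75 / 1e5)
  for (pos in c(1, 10, 20)) {
    freq <- table(factor(substr(lib$seq, pos, pos),
                         levels = c("A", "C", "G", "T"))) / 1e5
    expect_true(all(abs(freq - 0.25) < 3 * se), info = paste("pos", pos))
  }

  flanked <- simulate_library(50, core_length = 20, flank_5p = "GG", seed = 1)
  expect_true(all(nchar(flanked$seq) == 22))
  expect_true(all(startsWith(flanked$seq, "GG")))

  expect_equal(nrow(simulate_library(0, seed = 1)), 0)
  expect_error(simulate_library(10, flank_5p = "GX", seed = 1), "flanks")
})

test_that("generators are deterministic given the seed", {
  expect_identical(simulate_library(200, seed = 7),
                   simulate_library(200, seed = 7))
  lib <- simulate_library(500, seed = 7)
  m <- selection_model(reads_per_round = 500, rounds = 2)
  expect_identical(simulate_selection(lib, m, seed = 3),
                   simulate_selection(lib, m, seed = 3))
  expect_identical(simulate_titration(true_kd = 10, seed = 5),
                   simulate_titration(true_kd = 10, seed = 5))
  expect_identical(
    generate_gene_fixtures(50, terms = "T", seed = 9),
    generate_gene_fixtures(50, terms = "T", seed = 9)
  )
})

test_that("one selection round matches the closed-form expectation", {
  # 1% of reads carry a compact G4 element; theta = 0.1, background 0.01,
  # so matching reads weigh (theta + b) = 0.11 against b = 0.01 and the
  # expected post-round frequency is f(theta+b) / (f(theta+b) + (1-f)b)
  n <- 20000
  f <- 0.01
  seqs <- random_reads(n, 26, seed = 5)
  seqs <- ifelse(grepl("CTGT", seqs), random_reads(n, 12, seed = 6), seqs)
  planted <- seq_len(n * f)
  seqs[planted] <- paste0("AAAACC", "CTGTGAAT", "CCAAAA")
  lib <- tibble::tibble(read_id = as.character(seq_len(n)), seq = seqs)

  m <- selection_model(protein_concentration = 100,
                       class_kd = c(compact_G4 = 900),
                       background_retention = 0.01,
                       rounds = 1, reads_per_round = 4e5)
  out <- simulate_selection(lib, m, seed = 77)[[1]]
  got <- mean(match_pattern(out$seq, "CTGTGNAT"))

  f0 <- mean(match_pattern(seqs, "CTGTGNAT"))  # includes chance matches
  expected <- f0 * 0.11 / (f0 * 0.11 + (1 - f0) * 0.01)
  se <- sqrt(expected * (1 - expected) / 4e5)
  expect_lt(abs(got - expected), 3 * se)
})

test_that("uniform weights leave frequencies unchanged in expectation", {
  # no read matches any class: all weights equal the background
  seqs <- strrep(c("A", "C", "G"), 10)
  lib <- tibble::tibble(read_id = as.character(1:1000),
                        seq = rep(seqs, c(500, 300, 200)))
  m <- selection_model(class_kd = c(compact_G4 = 10),
                       background_retention = 0.5,
                       rounds = 1, reads_per_round = 2e5)
  out <- simulate_selection(lib, m, seed = 1)[[1]]
  freq <- table(out$seq) / 2e5
  se <- sqrt(0.5 * 0.5 / 2e5)
  expect_lt(abs(freq[[strrep("A", 10)]] - 0.5), 3 * se)
  expect_lt(abs(freq[[strrep("C", 10)]] - 0.3), 3 * se)
})

test_that("selection contract errors fire", {
  lib <- simulate_library(10, seed = 1)
  expect_error(selection_model(rounds = 0))
  expect_error(
    simulate_selection(lib[0, ], selection_model(), seed = 1), "nonempty")
  m <- selection_model(class_kd = c(no_such_class = 5))
  expect_error(simulate_selection(lib, m, patterns = puf_patterns(),
                                  seed = 1),
               "missing from class_kd")
})

test_that("occupancy weights are bounded and normalised", {
  lib <- simulate_library(2000, seed = 3)
  m <- selection_model()
  uniq <- unique(lib$seq)
  best <- pufselect:::.best_kd(uniq,
                               puf_patterns()[1:6 %% 2 == 1, ],
                               c(compact = 10.3, compact_G4 = 10.3,
                                 compact_A4 = 56.8))
  w <- pufselect:::.retention_weights(best, m)
  theta <- w - m$background_retention
  expect_true(all(theta >= 0 & theta <= 1))
  expect_equal(sum(w / sum(w)), 1, tolerance = 1e-12)
})

test_that("noiseless titrations reproduce the isotherm exactly", {
  tt <- simulate_titration(true_kd = 10, bmax = 1, noise_sd = 0,
                           n_replicates = 1, seed = 1)
  x <- tt$concentration_nM
  expect_equal(tt$signal, x / (10 + x))
  expect_equal(tt$signal[x == 0], 0)
  # half-saturation identity at X = Kd
  tt2 <- simulate_titration(true_kd = 250, bmax = 3, noise_sd = 0,
                            n_replicates = 1, seed = 1)
  expect_equal(tt2$signal[tt2$concentration_nM == 250], 1.5)
  expect_error(simulate_titration(true_kd = 10, noise_sd = -1, seed = 1),
               ">= 0")
  expect_error(simulate_titration(true_kd = 10, concentrations = c(1, 2, 4),
                                  seed = 1),
               "contain 0")
})

test_that("noisy titration signals are truncated at zero", {
  tt <- simulate_titration(true_kd = 10, noise_sd = 0.3, n_replicates = 5,
                           seed = 2)
  expect_true(all(tt$signal >= 0))
  expect_equal(nrow(tt), 5 * 15)
})

test_that("planted fixtures have full penetrance in the planted term", {
  fx <- generate_gene_fixtures(150, terms = c("T1", "T2"),
                               planted = c(T1 = "compact_G4"), seed = 21)
  t1_genes <- fx$annotations$gene_id[fx$annotations$term == "T1"]
  expect_gt(length(t1_genes), 0)
  seqs <- fx$genes$seq[fx$genes$gene_id %in% t1_genes]
  expect_true(all(match_pattern(seqs, "CTGTGNAT")))

  single <- generate_gene_fixtures(1, seed = 1)
  expect_equal(nrow(single$genes), 1)
  expect_equal(nrow(single$annotations), 0)

  expect_error(
    generate_gene_fixtures(5, terms = "A", planted = c(B = "compact_G4"),
                           seed = 1),
    "listed in")
})

test_that("chance element occurrence matches brute-force enumeration", {
  # exact match probability for the 7-nt core TGTRNAT in random 10-mers,
  # by enumerating all 4^10 sequences as base-4 digit arrays
  L <- 10L
  core <- c("T", "G", "T", "R", "N", "A", "T")
  n_all <- 4L^L
  digits <- matrix(0L, nrow = n_all, ncol = L)
  v <- 0:(n_all - 1)
  for (j in seq_len(L)) {
    digits[, j] <- v %% 4L
    v <- v %/% 4L
  }
  bases <- c("A", "C", "G", "T")
  allowed <- lapply(core, function(ch) match(oracle_sets[[ch]], bases) - 1L)
  hit <- rep(FALSE, n_all)
  for (s in 1:(L - length(core) + 1L)) {
    w <- rep(TRUE, n_all)
    for (j in seq_along(core)) {
      w <- w & digits[, s + j - 1L] %in% allowed[[j]]
    }
    hit <- hit | w
  }
  p_exact <- mean(hit)

  n_genes <- 2e5
  fx <- generate_gene_fixtures(n_genes, utr_length = L, seed = 31)
  p_obs <- mean(match_pattern(fx$genes$seq, "TGTRNAT"))
  se <- sqrt(p_exact * (1 - p_exact) / n_genes)
  expect_lt(abs(p_obs - p_exact), 3 * se)
})
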