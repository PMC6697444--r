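test_that("count_patterns counts reads, not occurrences, by default", {
  reads <- c(rep("AAACTGTGAATAAA", 3), random_reads(7, 14, seed = 2))
  pats <- puf_patterns()
  tbl <- count_patterns(reads, pats, "x")
  expect_equal(tbl$count[tbl$name == "compact_G4"], 3L)
  # counting is a pure function
  expect_identical(tbl, count_patterns(reads, pats, "x"))
  # brute-force check for the extended pattern on the same reads
  expect_equal(tbl$count[tbl$name == "extended_G4"],
               oracle_count_reads(reads, "CTGTGNNAT"))
  # a doubled element still counts once per read, occurrences twice
  dbl <- "CTGTGAATCTGTGAAT"
  expect_equal(count_patterns(dbl, pats, "x")$count[
    pats$name == "compact_G4"], 1L)
  expect_equal(count_patterns(dbl, pats, "x", mode = "occurrences")$count[
    pats$name == "compact_G4"], 2L)
})

test_that("adding reads never decreases any count; dedup collapses copies", {
  base <- random_reads(300, 26, seed = 8)
  more <- c(base, random_reads(100, 26, seed = 9))
  t1 <- count_patterns(base, dataset_label = "x")
  t2 <- count_patterns(more, dataset_label = "x")
  expect_true(all(t2$count >= t1$count))

  dup <- c(rep("AAACTGTGAATAAA", 5), "CCCCCCCCCCC")
  t3 <- count_patterns(dup, dataset_label = "x", dedup = TRUE)
  expect_equal(t3$count[t3$name == "compact_G4"], 1L)
})

test_that("RNA and DNA transliterations count identically", {
  dna <- c("AAACTGTGAATAAA", "GGCTGTAGGATTT", random_reads(50, 20, seed = 4))
  rna <- chartr("T", "U", dna)
  expect_equal(count_patterns(dna, dataset_label = "x")$count,
               count_patterns(rna, dataset_label = "x")$count)
})

test_that("compact:extended ratios reproduce the published table", {
  tbl <- seqrs_reference_counts()
  expect_equal(signif(compact_extended_ratio(tbl, "FBF-2", "A"), 2), 0.21)
  expect_equal(signif(compact_extended_ratio(tbl, "FBF-2", "G"), 2), 2.8)
  expect_equal(round(compact_extended_ratio(tbl, "Complex", "A"), 1), 0.7)
  expect_equal(signif(compact_extended_ratio(tbl, "Complex", "G"), 2), 1.1)
  expect_equal(signif(compact_extended_ratio(tbl, "CLIP", "A"), 2), 0.44)
  expect_equal(signif(compact_extended_ratio(tbl, "CLIP", "G"), 2), 1.1)
})

test_that("ratio edge cases behave per contract", {
  mk <- function(c_count, e_count) tibble::tibble(
    dataset = "d", element_class = c("compact", "extended"),
    base4 = "A", count = c(c_count, e_count)
  )
  expect_equal(compact_extended_ratio(mk(10L, 10L), "d", "A"), 1)
  expect_error(compact_extended_ratio(mk(10L, 0L), "d", "A"), "undefined")
  expect_error(compact_extended_ratio(mk(10L, 5L), "d", "G"), "exactly one")

  rt <- ratio_table(count_patterns(
    c("AAACTGTGAATAAA", "CCCCCCCCCCCCC"),
    puf_patterns()[puf_patterns()$base4 == "G", ], "d"))
  expect_true(is.na(rt$ratio[rt$base4 == "G"]))
})

test_that("PFM columns are normalised and IC follows the entropy formula", {
  # single aligned site: one-hot columns at 2 bits
  one <- build_pfm("AACTGTGAATCCC", window = c(-2, 9))
  expect_equal(one$n_sites, 1)
  expect_true(all(abs(colSums(one$prob) - 1) < 1e-9))
  expect_true(all(abs(one$ic - 2) < 1e-12))

  # two sites differing only at +5: 1 bit there, 2 bits elsewhere
  two <- build_pfm(c("AACTGTGAATCCC", "AACTGTGCATCCC"), window = c(-2, 9))
  expect_equal(two$n_sites, 2)
  expect_equal(unname(two$ic[["+5"]]), 1)
  expect_true(all(abs(two$ic[names(two$ic) != "+5"] - 2) < 1e-12))
  expect_true(all(two$ic >= 0 & two$ic <= 2))

  # reads whose window leaves the read are dropped; none left -> error
  expect_error(build_pfm("CTGTGAAT"), "window")
  # first match per read is used
  first <- build_pfm("AACTGTGAATCCCCCCCTGTGCATCCC", window = c(-2, 9))
  expect_equal(unname(first$prob["A", "+5"]), 1)
})

test_that("PFM window coordinates skip position zero", {
  pfm <- build_pfm("AACTGTGAATCCC", window = c(-2, 9))
  expect_equal(colnames(pfm$prob),
               c("-2", "-1", "+1", "+2", "+3", "+4", "+5", "+6", "+7",
                 "+8", "+9"))
  # -1 is the upstream C, +1..+3 the TGT anchor
  expect_equal(unname(pfm$prob["C", "-1"]), 1)
  expect_equal(unname(pfm$prob["T", "+1"]), 1)
  expect_equal(unname(pfm$prob["G", "+2"]), 1)
  expect_equal(unname(pfm$prob["T", "+3"]), 1)
})

test_that("tidy() on a PFM returns a long tibble", {
  pfm <- build_pfm(c("AACTGTGAATCCC", "AACTGTGCATCCC"), window = c(-2, 9))
  td <- tidy(pfm)
  expect_s3_class(td, "tbl_df")
  expect_setequal(names(td), c("base", "position", "prob", "ic"))
  expect_equal(nrow(td), 4 * 11)
})
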