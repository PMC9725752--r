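profile_fixture <- function(pct_dfi, pct_dci) {
  dfi <- data.frame(dfi = pct_dfi, pct_dfi = pct_dfi)
  class(dfi) <- c("dfi_profile", "data.frame")
  dci <- data.frame(dci = pct_dci, pct_dci = pct_dci)
  class(dci) <- c("dci_profile", "data.frame")
  list(dfi = dfi, dci = dci)
}

test_that("the four-category worked examples classify as defined", {
  p <- profile_fixture(pct_dfi = c(0.15, 0.9, 0.5, 0.99),
                       pct_dci = c(0.8, 0.3, 0.8, 0.1))
  tab <- classify_icdc(p$dfi, p$dci,
                       coevo_scores = c(0.7, 0.2, 0.9, 0.65),
                       binding_set = 4L)
  expect_s3_class(tab, "icdc_table")
  expect_equal(tab$category[tab$residue == 1], "(1,1)")   # rigid+coupled+coevolved
  expect_equal(tab$category[tab$residue == 2], "(0,0)")   # flexible, uncoupled
  expect_equal(tab$category[tab$residue == 3], "unclassified")
  expect_false(4L %in% tab$residue)                       # binding site excluded
})

test_that("threshold edges are inclusive as stated", {
  p <- profile_fixture(pct_dfi = c(0.2, 0.7, 0.3), pct_dci = c(0.7, 0.3, 0.7))
  tab <- classify_icdc(p$dfi, p$dci, coevo_scores = c(0.6, 0.59, 0.6),
                       binding_set = 3L)
  expect_equal(tab$category, c("(1,1)", "(0,0)"))
})

test_that("every position gets exactly one label and counts partition", {
  set.seed(21)
  n <- 40L
  p <- profile_fixture(percentile_rank(stats::runif(n)),
                       percentile_rank(stats::runif(n)))
  cs <- stats::runif(n)
  binding <- c(5L, 17L)
  tab <- classify_icdc(p$dfi, p$dci, cs, binding)
  expect_equal(nrow(tab), n - length(binding))
  expect_true(all(tab$category %in%
    c("(1,1)", "(1,0)", "(0,1)", "(0,0)", "unclassified")))
  expect_equal(sum(table(tab$category)), n - length(binding))
  # nearest-extreme mode leaves no unclassified positions
  tn <- classify_icdc(p$dfi, p$dci, cs, binding, mode = "nearest")
  expect_false(any(tn$category == "unclassified"))
})

test_that("threshold moves are monotone in the expected direction", {
  set.seed(33)
  n <- 60L
  p <- profile_fixture(percentile_rank(stats::runif(n)),
                       percentile_rank(stats::runif(n)))
  cs <- stats::runif(n)
  t0 <- classify_icdc(p$dfi, p$dci, cs, 1L)
  lo_dci <- classify_icdc(p$dfi, p$dci, cs, 1L,
                          thresholds = list(dci = 0.5))
  expect_true(all(which(t0$dyn_bit == 1L) %in% which(lo_dci$dyn_bit == 1L)))
  hi_coevo <- classify_icdc(p$dfi, p$dci, cs, 1L,
                            thresholds = list(coevo = 0.8))
  expect_true(all(which(hi_coevo$coevo_bit == 1L) %in%
                  which(t0$coevo_bit == 1L)))
})

test_that("unmapped positions fall back to zero coupling with a note", {
  p <- profile_fixture(c(0.1, 0.9), c(0.9, 0.1))
  expect_error(classify_icdc(p$dfi, p$dci, c(NA, NA), integer(0)),
               "binding_set is empty")
  expect_message(tab <- classify_icdc(p$dfi, p$dci, c(NA, 0.9), 2L),
                 "mapped MSA column")
  expect_equal(tab$coevo_score, 0)
  expect_equal(tab$coevo_bit, 0L)
})

test_that("binding-site MSA filtering keeps compatible sequences", {
  seqs <- c(ref = "AKDEFG", s1 = "AKDEFG", s2 = "AKDYFG", s3 = "GGGGGG")
  m <- msa_from_sequences(seqs)
  bind_cols <- c(1L, 2L, 3L, 5L)
  strict <- filter_msa_by_binding_site(m, bind_cols, min_identity = 1)
  expect_setequal(strict$ids, c("ref", "s1", "s2"))   # s2 differs outside site
  all_in <- filter_msa_by_binding_site(m, bind_cols, min_identity = 0)
  expect_setequal(all_in$ids, names(seqs))

  # 10-sequence fixture against a per-sequence counting oracle
  set.seed(7)
  base <- "AKDEFGHIKL"
  pool <- vapply(1:9, function(i) {
    ch <- strsplit(base, "")[[1]]
    nmut <- sample(0:4, 1)
    pos <- sample(10, nmut)
    ch[pos] <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                              ch[pos]), nmut)
    paste(ch, collapse = "")
  }, "")
  seqs10 <- c(ref = base, stats::setNames(pool, paste0("s", 1:9)))
  m10 <- msa_from_sequences(seqs10)
  bc <- c(2L, 4L, 7L, 9L)
  got <- filter_msa_by_binding_site(m10, bc, min_identity = 0.75)
  chars <- do.call(rbind, strsplit(seqs10, ""))
  match_frac <- rowSums(chars[, bc] ==
                        rep(chars[1, bc], each = 10)) / length(bc)
  want <- names(seqs10)[match_frac >= 0.75 | seq_len(10) == 1L]
  expect_setequal(got$ids, want)
})

test_that("similarity classes admit conservative binding-site variants", {
  seqs <- c(ref = "AKDE", s1 = "ARDE", s2 = "AWDE")
  m <- msa_from_sequences(seqs)
  exact <- filter_msa_by_binding_site(m, 1:4, min_identity = 1)
  expect_setequal(exact$ids, "ref")
  classy <- filter_msa_by_binding_site(m, 1:4, min_identity = 1,
                                       mode = "class")
  expect_setequal(classy$ids, c("ref", "s1"))   # K~R conservative, K!~W
})

test_that("substitution proposals follow weighted frequencies", {
  # column: 50% A (wt), 30% K, 20% Y under uniform weights
  seqs <- c(ref = "A", s1 = "A", s2 = "A", s3 = "A", s4 = "A",
            s5 = "K", s6 = "K", s7 = "K", s8 = "Y", s9 = "Y")
  m <- msa_from_sequences(seqs)
  w <- structure(list(weights = rep(1, 10), meff = 10),
                 class = "sequence_weights")
  got <- propose_substitutions(m, w, position = 1L, min_weighted_freq = 0.25)
  expect_equal(got$substitution, "K")
  expect_equal(got$weighted_frequency, 0.3)
  expect_equal(got$supporting_sequences, 3L)

  all3 <- propose_substitutions(m, w, 1L, min_weighted_freq = 0.05)
  expect_equal(all3$substitution, c("K", "Y"))

  # wild-type-only column proposes nothing
  mono <- msa_from_sequences(c(ref = "G", s1 = "G"))
  wm <- structure(list(weights = c(1, 1), meff = 2),
                  class = "sequence_weights")
  expect_equal(nrow(propose_substitutions(mono, wm, 1L)), 0L)
  expect_error(propose_substitutions(mono, wm, 99L), "not mapped")

  # duplicated sequences: weighted tally oracle
  seqs_d <- c(ref = "A", s1 = "K", s2 = "K", s3 = "Y")
  md <- msa_from_sequences(seqs_d)
  wd <- structure(list(weights = c(1, 0.5, 0.5, 1), meff = 3),
                  class = "sequence_weights")
  gd <- propose_substitutions(md, wd, 1L, min_weighted_freq = 0)
  expect_equal(gd$weighted_frequency[gd$substitution == "K"], 1 / 3)
  expect_equal(gd$weighted_frequency[gd$substitution == "Y"], 1 / 3)
})
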