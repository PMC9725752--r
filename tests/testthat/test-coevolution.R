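uniform_weights <- function(m) {
  structure(list(weights = rep(1, m), meff = m), class = "sequence_weights")
}

test_that("FASTA reading builds the reference column map", {
  f <- write_lines_tmp(c(">refseq", "ACDE", ">s1", "ACDF", ">s2", "GCDE"),
                       ".fasta")
  m <- read_msa(f, format = "fasta", reference_id = "refseq")
  expect_equal(m$L, 4L)
  expect_equal(m$column_map, 1:4)
  m10 <- read_msa(f, reference_id = "refseq", offset = 10L)
  expect_equal(m10$column_map, 11:14)
  expect_error(read_msa(f, reference_id = "nope"), "available")
})

test_that("gapped reference columns are unmapped", {
  m <- msa_from_sequences(c(ref = "A-CD", s1 = "AGCD", s2 = "AGC-"))
  expect_equal(m$column_map, c(1L, NA, 2L, 3L))
})

test_that("Stockholm input round-trips the FASTA fixture", {
  seqs <- c(ref = "ACDE", s1 = "AC-E", s2 = "GCDE")
  ff <- write_lines_tmp(paste0(">", names(seqs), "\n", seqs), ".fasta")
  sf <- write_lines_tmp(c("# STOCKHOLM 1.0",
                          paste(names(seqs), seqs), "//"), ".sto")
  m_fa <- read_msa(ff, format = "fasta", reference_id = "ref")
  m_st <- read_msa(sf, format = "stockholm", reference_id = "ref")
  expect_identical(m_fa$mat, m_st$mat)
  expect_identical(m_fa$column_map, m_st$column_map)
})

test_that("ragged alignments are rejected", {
  expect_error(msa_from_sequences(c(a = "ACD", b = "AC")), "ragged")
})

test_that("sequence weights count identity neighborhoods", {
  m4 <- msa_from_sequences(c(a = "ACDE", b = "ACDE", c = "ACDE", d = "ACDE"))
  w <- compute_weights(m4, 0.8)
  expect_equal(w$weights, rep(0.25, 4))
  expect_equal(w$meff, 1)

  md <- msa_from_sequences(c(a = "ACDE", b = "GHIK", c = "LMNP", d = "QRST"))
  wd <- compute_weights(md, 0.8)
  expect_equal(wd$weights, rep(1, 4))
  expect_equal(wd$meff, 4)

  # mixed: duplicates plus uniques, against an O(M^2) counting oracle
  seqs <- c(a = "ACDEF", b = "ACDEF", c = "GHIKL", d = "MNPQR")
  mm <- msa_from_sequences(seqs)
  wm <- compute_weights(mm, 0.8)
  chars <- do.call(rbind, strsplit(seqs, ""))
  oracle <- vapply(1:4, function(i) {
    nb <- 0
    for (j in 1:4) {
      both <- chars[i, ] != "-" & chars[j, ] != "-"
      if (sum(chars[i, both] == chars[j, both]) / sum(both) >= 0.8)
        nb <- nb + 1
    }
    1 / nb
  }, 0)
  expect_equal(wm$weights, oracle)
})

test_that("mutual information matches closed forms and the summation oracle", {
  # perfectly covarying uniform binary columns: exactly 1 bit
  m <- msa_from_sequences(c(r1 = "AC", r2 = "CA", r3 = "AC", r4 = "CA"))
  cm <- compute_mi(m, uniform_weights(4), pseudocount = 0, min_effective = 1)
  expect_equal(cm$raw_mi[1, 2], 1, tolerance = 1e-12)

  # constant column: zero MI
  mc <- msa_from_sequences(c(r1 = "AA", r2 = "AC", r3 = "AG", r4 = "AW"))
  cmc <- compute_mi(mc, uniform_weights(4), pseudocount = 0, min_effective = 1)
  expect_equal(cmc$raw_mi[1, 2], 0, tolerance = 1e-12)

  # 3-symbol joint table with unequal weights vs direct-sum oracle
  seqs <- c(a = "AD", b = "AE", c = "CD", d = "CE", e = "GD", f = "GG")
  m3 <- msa_from_sequences(seqs)
  w <- structure(list(weights = c(1, .5, .5, 1, .25, 1), meff = 4.25),
                 class = "sequence_weights")
  cm3 <- compute_mi(m3, w, pseudocount = 0.5, min_effective = 1)
  want <- oracle_mi(m3$mat[, 1], m3$mat[, 2], w$weights, lambda = 0.5)
  expect_equal(cm3$raw_mi[1, 2], want, tolerance = 1e-12)
})

test_that("gapped rows are excluded pairwise and sparse pairs invalidated", {
  seqs <- c(a = "AC-", b = "CA-", c = "AC-", d = "CAA")
  m <- msa_from_sequences(seqs)
  cm <- compute_mi(m, uniform_weights(4), pseudocount = 0, min_effective = 2)
  expect_true(cm$valid[1, 2])
  expect_false(cm$valid[1, 3])          # only one ungapped row at column 3
  expect_false(any(diag(cm$valid)))
  expect_error(compute_mi(m, uniform_weights(4), min_effective = 100),
               "no valid")
})

test_that("average-product correction removes constant backgrounds", {
  L <- 4L
  base <- list(L = L, raw_mi = matrix(0.7, L, L),
               corrected = matrix(NA_real_, L, L),
               normalized = matrix(NA_real_, L, L),
               valid = !diag(L) > 0)
  class(base) <- "coupling_matrix"
  cc <- apc_correct(base)
  expect_equal(cc$corrected[upper.tri(cc$corrected)], rep(0, 6),
               tolerance = 1e-12)

  # single valid pair: correction equals the pair's own MI
  one <- base
  one$valid[] <- FALSE
  one$valid[1, 2] <- one$valid[2, 1] <- TRUE
  one$raw_mi[1, 2] <- one$raw_mi[2, 1] <- 0.42
  c1 <- apc_correct(one)
  expect_equal(c1$corrected[1, 2], 0, tolerance = 1e-12)

  # planted high-MI pair against hand-evaluated APC
  mi <- matrix(0.1, L, L)
  mi[1, 3] <- mi[3, 1] <- 0.9
  planted <- base
  planted$raw_mi <- mi
  cp <- apc_correct(planted)
  col_mean <- vapply(1:L, function(a) mean(mi[a, -a]), 0)
  mean_all <- mean(mi[upper.tri(mi)])
  for (a in 1:3) for (b in (a + 1):4)
    expect_equal(cp$corrected[a, b],
                 mi[a, b] - col_mean[a] * col_mean[b] / mean_all,
                 tolerance = 1e-12)
})

test_that("rank normalization spans (0, 1] and crowns the planted pair", {
  L <- 3L
  cm <- list(L = L, raw_mi = matrix(0, L, L),
             corrected = rbind(c(NA, .1, .3), c(.1, NA, .2), c(.3, .2, NA)),
             normalized = matrix(NA_real_, L, L), valid = !diag(L) > 0)
  class(cm) <- "coupling_matrix"
  nn <- normalize_coupling(cm)
  expect_equal(nn$normalized[1, 2], 1 / 3)
  expect_equal(nn$normalized[2, 3], 2 / 3)
  expect_equal(nn$normalized[1, 3], 1)
  expect_equal(nn$normalized, t(nn$normalized))

  planted <- data.frame(col_a = 2L, col_b = 9L, strength = 1)
  msa <- make_msa(200, 12, planted, conservation = 0.7, seed = 42)
  cp <- normalize_coupling(apc_correct(compute_mi(msa, compute_weights(msa))))
  expect_equal(cp$normalized[2, 9], 1)
  expect_equal(which.max(coupling_to_site(cp, 9L)), 2L)
})

test_that("MI is symmetric, nonnegative, and duplication-invariant", {
  msa <- make_msa(60, 8, conservation = 0.6, seed = 9)
  w <- compute_weights(msa)
  cm <- normalize_coupling(apc_correct(compute_mi(msa, w)))
  ut <- upper.tri(cm$raw_mi)
  expect_true(all(cm$raw_mi[ut & cm$valid] >= -1e-12))
  expect_equal(cm$raw_mi, t(cm$raw_mi))
  expect_equal(cm$corrected, t(cm$corrected))

  dup <- msa_from_sequences(
    stats::setNames(rep(msa$seqs, each = 3),
                    paste0(rep(msa$ids, each = 3), "_", 1:3)),
    reference_id = paste0(msa$ids[1], "_1"))
  wd <- compute_weights(dup)
  cmd <- apc_correct(compute_mi(dup, wd))
  expect_equal(cmd$raw_mi, cm$raw_mi, tolerance = 1e-12)
  expect_equal(cmd$corrected, cm$corrected, tolerance = 1e-12)
})
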