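test_that("column counts match hand tallies and conserve group size", {
  aln <- labeled_alignment(paste0("s", 1:4), c("AA", "A-", "AA", "VX"),
                           rep(c("tr", "est"), 2))
  cc <- column_counts(aln, 1)
  expect_equal(unname(cc$counts[c("A", "V")]), c(3, 1))
  expect_equal(cc$n_gap, 0)
  cc2 <- column_counts(aln, 2)  # gap + ambiguity code both non-countable
  expect_equal(unname(cc2$counts["A"]), 2)
  expect_equal(cc2$n_gap, 2)
  expect_equal(sum(cc2$counts) + cc2$n_gap, cc2$n_total)

  # conservation property on many random columns
  aln2 <- random_alignment(30, 40, gap_prob = 0.3, seed = 9)
  for (col in seq_len(40)) {
    for (g in list("tr", c("est", "putative"))) {
      cc <- column_counts(aln2, col, g)
      chars <- substring(aln2$seq[aln2$group %in% g], col, col)
      expect_equal(sum(cc$counts) + cc$n_gap, length(chars))
      expect_equal(unname(cc$counts["A"]), sum(chars == "A"))
    }
  }
})

test_that("pseudo-count correction follows the mixing formula", {
  pc0 <- pseudo_count_model(0)
  pc2 <- pseudo_count_model(2)
  counts <- setNames(c(9, rep(0, 18), 1), pc2$alphabet)  # 9 A, 1 V
  cc <- structure(list(column = 1L, counts = counts, n_total = 10, n_gap = 0),
                  class = "column_counts")
  f0 <- corrected_frequencies(cc, pc0)
  expect_equal(unname(f0[c("A", "V")]), c(0.9, 0.1))
  expect_equal(sum(f0), 1)

  f2 <- corrected_frequencies(cc, pc2)
  expect_equal(sum(f2), 1, tolerance = 1e-12)
  expect_true(all(f2 > 0))

  # direct formula evaluation as oracle, single observed residue
  counts1 <- setNames(c(rep(0, 3), 4, rep(0, 16)), pc2$alphabet)  # 4 x D
  cc1 <- structure(list(column = 1L, counts = counts1, n_total = 4, n_gap = 0),
                   class = "column_counts")
  f <- corrected_frequencies(cc1, pc2)
  manual <- (counts1 + 2 * pc2$cond[, "D"]) / (4 + 2)
  expect_equal(unname(f), unname(manual), tolerance = 1e-15)

  # all-gap column
  empty <- structure(list(column = 1L, counts = setNames(rep(0, 20),
                                                         pc2$alphabet),
                          n_total = 3, n_gap = 3), class = "column_counts")
  expect_error(corrected_frequencies(empty, pc0), "empty column")
  expect_equal(sum(corrected_frequencies(empty, pc2)), 1, tolerance = 1e-12)

  # strict mode divides by the full group size, so gapped columns sum < 1
  gapped <- structure(list(column = 1L, counts = counts1, n_total = 6,
                           n_gap = 2), class = "column_counts")
  expect_lt(sum(corrected_frequencies(gapped, pc2, strict_nall = TRUE)), 1)
})

test_that("column entropy matches analytic values", {
  expect_equal(column_entropy(c(1, rep(0, 19))), 0, tolerance = 1e-9)
  expect_equal(column_entropy(rep(1 / 20, 20)), log10(20), tolerance = 1e-9)
  expect_equal(column_entropy(c(0.9, 0.1)),
               -(0.9 * log10(0.9) + 0.1 * log10(0.1)), tolerance = 1e-9)
  expect_equal(column_entropy(c(0.9, 0.1)), 0.141182, tolerance = 1e-5)
  expect_error(column_entropy(c(-0.1, 1.1)), "negative")
})

test_that("entropy profile composes group entropies and their difference", {
  pc0 <- pseudo_count_model(0)
  # 4 tr all 'N'; 20 others uniform over the alphabet
  others <- pc0$alphabet
  aln <- labeled_alignment(c(paste0("t", 1:4), paste0("o", 1:20)),
                           c(rep("N", 4), others),
                           c(rep("tr", 4), rep("putative", 20)))
  prof <- entropy_profile(aln, pc0)
  expect_equal(prof$E_tr, 0, tolerance = 1e-9)
  expect_equal(prof$E_other, log10(20), tolerance = 1e-9)
  expect_equal(prof$delta, log10(20), tolerance = 1e-9)

  # identical composition in both groups -> delta 0
  aln2 <- labeled_alignment(paste0("s", 1:8),
                            rep(c("AAVL", "AVLL"), 4),
                            rep(c("tr", "est"), each = 4))
  prof2 <- entropy_profile(aln2, pc0)
  expect_equal(prof2$delta, rep(0, 4), tolerance = 1e-12)
})

test_that("entropy profile equals a naive per-column reimplementation", {
  pc <- pseudo_count_model(2)
  aln <- random_alignment(30, 50, gap_prob = 0.25, seed = 17)
  prof <- entropy_profile(aln, pc)
  oracle <- naive_entropy_profile(aln, pc)
  expect_equal(prof$E_tr, oracle$E_tr, tolerance = 1e-12)
  expect_equal(prof$E_other, oracle$E_other, tolerance = 1e-12)
  expect_equal(prof$delta, oracle$delta, tolerance = 1e-12)
  # strict denominator mode agrees with its own naive counterpart
  expect_equal(entropy_profile(aln, pc, strict_nall = TRUE)$delta,
               naive_entropy_profile(aln, pc, strict_nall = TRUE)$delta,
               tolerance = 1e-12)
})

test_that("swapping group labels negates delta at every column", {
  aln <- random_alignment(20, 30, seed = 5,
                          groups = rep(c("tr", "est"), 10))
  swapped <- labeled_alignment(aln$id, aln$seq,
                               ifelse(aln$group == "tr", "est", "tr"))
  pc <- pseudo_count_model(2)
  expect_equal(entropy_profile(aln, pc)$delta,
               -entropy_profile(swapped, pc)$delta, tolerance = 1e-12)
})

test_that("entropy of a conserved column is non-decreasing in the pseudo-count", {
  counts <- setNames(c(rep(0, 5), 6, rep(0, 14)), AA <- pseudo_count_model(0)$alphabet)
  cc <- structure(list(column = 1L, counts = counts, n_total = 6, n_gap = 0),
                  class = "column_counts")
  es <- vapply(c(0, 0.5, 1, 2, 5, 10), function(B)
    column_entropy(corrected_frequencies(cc, pseudo_count_model(B))), 0)
  expect_true(all(diff(es) >= -1e-12))
  expect_equal(es[1], 0)
})

test_that("candidate ranking is deterministic with index tie-breaks and exclusions", {
  prof <- tibble::tibble(column = 1:4, delta = c(0.1, 1.3, 0.0, 1.3),
                         E_tr = 0, E_other = 0)
  top <- rank_candidates(prof, k = 2)
  expect_equal(top$column, c(2L, 4L))
  expect_equal(top$rank, 1:2)
  # exclusion promotes the next column
  top2 <- rank_candidates(prof, k = 2, exclude_columns = 2)
  expect_equal(top2$column, c(4L, 1L))
  # k beyond eligible columns returns all, with a warning
  expect_warning(all4 <- rank_candidates(prof, k = 10), "eligible")
  expect_equal(nrow(all4), 4)
  # optional tr-entropy ceiling
  prof$E_tr <- c(0, 0.9, 0, 0)
  expect_equal(rank_candidates(prof, k = 1, max_E_tr = 0.5)$column, 4L)
})

test_that("esterase-absence filter follows set membership with gap = absence", {
  aln <- labeled_alignment(
    c("t1", "t2", "e1", "e2", "e3"),
    c("NDA", "RDA", "SD-", "T--", "AEG"),
    c("tr", "tr", "est", "est", "est"))
  cand <- tibble::tibble(column = 1:3)
  out <- est_absence_filter(aln, cand)
  expect_equal(out$tr_residues, c("N,R", "D", "A"))
  # col1: est {S,T,A} vs tr {N,R} -> absent; col2: est carries D -> present
  expect_equal(out$absent_from_est, c(TRUE, FALSE, TRUE))
  # column where every est sequence is gapped counts as absent
  aln2 <- labeled_alignment(c("t1", "e1", "e2"), c("D", "-", "-"),
                            c("tr", "est", "est"))
  expect_true(est_absence_filter(aln2, tibble::tibble(column = 1))$absent_from_est)
})

test_that("sequence status classification matches a brute-force tally", {
  aln <- labeled_alignment(
    c("a", "b", "c", "d"),
    c("N-D", "NAA", "-AD", "SAA"),
    c("tr", "est", "putative", "est"))
  st <- classify_sequences(aln, 1, c("N", "R"), 3, "D")
  expect_equal(st$status, c("both", "pos1_only", "pos2_only", "neither"))

  aln2 <- random_alignment(40, 10, seed = 8)
  st2 <- classify_sequences(aln2, 2, c("A", "G"), 7, c("D", "E"))
  chars2 <- substring(aln2$seq, 2, 2)
  chars7 <- substring(aln2$seq, 7, 7)
  brute <- dplyr::case_when(
    chars2 %in% c("A", "G") & chars7 %in% c("D", "E") ~ "both",
    chars2 %in% c("A", "G") ~ "pos1_only",
    chars7 %in% c("D", "E") ~ "pos2_only",
    .default = "neither")
  expect_equal(st2$status, brute)
})
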