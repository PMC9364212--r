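test_that("pairwise identity counts matches over mutually ungapped sites", {
  expect_equal(pairwise_identity("ACGT", "ACGA"), 75)
  expect_equal(pairwise_identity("AC-T", "ACGT"), 100)
  expect_equal(pairwise_identity("WYKR", "WYKR"), 100)
  expect_error(pairwise_identity("---A", "A---"), "shared")
  expect_error(pairwise_identity("AC", "ACG"), "equal length")
})

test_that("identity is symmetric and invariant to shared gap columns", {
  a <- "MKV-LLAG"
  b <- "MRV-ILAG"
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  # insert a gap column into both sequences at the same position
  a2 <- "MKV--LLAG"; b2 <- "MRV--ILAG"
  expect_equal(pairwise_identity(a, b), pairwise_identity(a2, b2))
})

test_that("identity matrices are symmetric, 100 on the diagonal, order-invariant", {
  aln <- c(s1 = "MKVLL", s2 = "MKVLV", s3 = "MRILV")
  m <- identity_matrix(aln)
  expect_equal(diag(m), c(s1 = 100, s2 = 100, s3 = 100))
  expect_equal(m, t(m))
  m2 <- identity_matrix(aln[c(3, 1, 2)])
  expect_equal(m2[rownames(m), colnames(m)], m)
})

test_that("aligned FASTA files are read through Biostrings", {
  skip_if_not_installed("Biostrings")
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "MKV-L", ">s2", "MKVAL", ">s3", "MRVAL"), fa)
  m <- identity_matrix(fa)
  expect_equal(m["s1", "s2"], 100)
  expect_equal(m["s2", "s3"], 80)
})

test_that("identical matrices give p = 1 and degenerate median intervals", {
  aln <- c(s1 = "MKVLL", s2 = "MKVLV", s3 = "MRILV", s4 = "MRILL")
  m <- identity_matrix(aln)
  res <- paired_similarity_test(m, m, B = 200)  # 6 pairs: no small-n warning
  expect_equal(res$test$p_value, 1)
  expect_warning(paired_similarity_test(m[1:3, 1:3], m[1:3, 1:3], B = 200),
                 "fewer than 6")
  const <- matrix(50, 4, 4, dimnames = dimnames(m)); diag(const) <- 100
  resc <- suppressWarnings(paired_similarity_test(const, const, B = 200))
  expect_equal(resc$medians$lo, resc$medians$hi)
  expect_equal(resc$medians$median, c(50, 50))
})

test_that("a uniform 10-point offset over 20 pairs attains the minimal exact p", {
  # abstract identity matrices whose off-diagonals differ by a constant +10
  set.seed(12)
  n <- 7  # 21 strain pairs
  ids <- sprintf("p%02d", 1:n)
  base <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- runif(n * (n - 1) / 2, 40, 60)
  base[upper.tri(base)] <- vals
  base <- base + t(base); diag(base) <- 100
  up <- base + 10; diag(up) <- 100
  res <- paired_similarity_test(up, base, B = 200)
  expect_equal(res$test$n_pairs, 21)
  expect_equal(res$test$p_value, 2 / 2^21)
})

test_that("multi-copy strains are averaged per strain pair before pairing", {
  # strain X carries two copies x1, x2; identities to strain Y should enter
  # as their mean
  ids <- c("x1", "x2", "y", "z")
  m <- matrix(100, 4, 4, dimnames = list(ids, ids))
  m["x1", "y"] <- m["y", "x1"] <- 40
  m["x2", "y"] <- m["y", "x2"] <- 60
  m["x1", "z"] <- m["z", "x1"] <- 70
  m["x2", "z"] <- m["z", "x2"] <- 70
  m["y", "z"] <- m["z", "y"] <- 55
  m["x1", "x2"] <- m["x2", "x1"] <- 90
  strain_of <- c(x1 = "X", x2 = "X", y = "Y", z = "Z")
  pairs <- ciphylo:::strain_pair_identities(m, strain_of)
  expect_equal(nrow(pairs), 3)  # within-strain X pair dropped
  expect_equal(pairs$identity[pairs$strain_a == "X" & pairs$strain_b == "Y"], 50)
  expect_equal(pairs$identity[pairs$strain_a == "X" & pairs$strain_b == "Z"], 70)
})

test_that("TM scores are orientation-averaged and correlate via the t transform", {
  tm <- tibble::tibble(
    id_a = c("a", "b", "a", "c", "b", "c"),
    id_b = c("b", "a", "c", "a", "c", "b"),
    score_ab = c(0.5, 0.6, 0.7, 0.9, 0.4, 0.5),
    score_ba = c(0.6, 0.5, 0.9, 0.7, 0.5, 0.4)
  )
  sym <- symmetrize_tm_scores(tm)
  expect_equal(nrow(dplyr::distinct(sym)), 3)
  expect_equal(sort(unique(sym$tm_score)), c(0.45, 0.55, 0.8))

  set.seed(3)
  ids <- letters[1:4]
  ident <- matrix(runif(16, 30, 90), 4, 4, dimnames = list(ids, ids))
  ident <- (ident + t(ident)) / 2; diag(ident) <- 100
  prs <- t(combn(ids, 2))
  tm6 <- tibble::tibble(
    id_a = prs[, 1], id_b = prs[, 2],
    tm_score = 0.005 * ident[prs] + rnorm(6, 0, 0.02)
  )
  res <- structure_sequence_correlation(tm6, ident)
  expect_equal(res$n, 6)
  expect_equal(res$r.squared, res$r^2)
  # closed-form t transform oracle
  tstat <- res$r * sqrt((6 - 2) / (1 - res$r^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 6 - 2))
  # reversed ranks give a negative correlation
  tm_rev <- tm6; tm_rev$tm_score <- -tm6$tm_score
  expect_lt(structure_sequence_correlation(tm_rev, ident)$r, 0)
  # perfect linearity
  tm_lin <- tm6; tm_lin$tm_score <- 0.01 * ident[prs]
  expect_equal(structure_sequence_correlation(tm_lin, ident)$r.squared, 1)
})
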