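test_that("preprocessing applies depth, query-gap and gappy filters in order", {
  m <- msa(c("A-C", "AGC"))
  enc <- preprocess_encoded(encode_msa(m), neff_options())
  expect_equal(ncol(enc$matrix), 2L)
  expect_equal(enc$column_map, c(1L, 3L))
  expect_equal(unname(enc$columns_removed["query_gap"]), 1L)

  keep <- preprocess_encoded(encode_msa(m), neff_options(keep_query_gaps = TRUE))
  expect_equal(ncol(keep$matrix), 3L)

  # column with 3 gaps among 4 rows: 0.75 > 0.5 -> dropped
  m2 <- msa(c("AC", "A-", "A-", "A-"))
  enc2 <- preprocess_encoded(encode_msa(m2),
                             neff_options(gap_cutoff = 0.5, keep_query_gaps = TRUE))
  expect_equal(ncol(enc2$matrix), 1L)
  expect_equal(unname(enc2$columns_removed["gappy"]), 1L)
  # 0.75 is not > 0.75: strict comparison keeps the column
  enc3 <- preprocess_encoded(encode_msa(m2),
                             neff_options(gap_cutoff = 0.75, keep_query_gaps = TRUE))
  expect_equal(ncol(enc3$matrix), 2L)

  m5 <- rand_msa(5, 10, gap_p = 0)
  enc5 <- preprocess_encoded(encode_msa(m5), neff_options(depth = 2))
  expect_equal(nrow(enc5$matrix), 2L)
  expect_equal(enc5$ids, m5$ids[1:2])
  # depth cap always retains the query
  m5q <- msa(m5$seqs, query_index = 5L)
  enc5q <- preprocess_encoded(encode_msa(m5q), neff_options(depth = 2),
                              query_row = 5L)
  expect_equal(enc5q$ids, m5$ids[c(1, 5)])
  expect_equal(enc5q$query_row, 2L)

  expect_error(preprocess_encoded(encode_msa(msa(c("--", "AC"))), neff_options()),
               class = "neffr_empty_error")
})

test_that("pairwise similarity matches the stated constructions", {
  enc <- encode_msa(msa(c("ACDEF", "ACDEF")))
  expect_equal(pairwise_similarity(enc, 1, 2), 1.0)
  enc2 <- encode_msa(msa(c("ACDEF", "ACDEG")))
  expect_equal(pairwise_similarity(enc2, 1, 2), 0.8)
  # gap-gap counts as a match in symmetric mode
  enc3 <- encode_msa(msa(c("AC--", "AC--")), non_standard = "as_standard")
  expect_equal(pairwise_similarity(enc3, 1, 2), 1.0)
  # asymmetric: normalized by each target's non-gap length
  enc4 <- encode_msa(msa(c("AC--", "ACGT")))
  s <- pairwise_similarity(enc4, 1, 2, symmetric = FALSE)
  expect_equal(unname(s["ij"]), 0.5)
  expect_equal(unname(s["ji"]), 1.0)
  # symmetric mode is symmetric for random pairs
  set.seed(41)
  encr <- encode_msa(rand_msa(6, 12, gap_p = 0.2))
  for (i in 1:5) expect_equal(pairwise_similarity(encr, i, i + 1),
                              pairwise_similarity(encr, i + 1, i))
})

test_that("sequence weights reproduce the worked identity-cluster examples", {
  w1 <- sequence_weights(encode_msa(msa(rep("ACDEF", 3))))
  expect_equal(w1, rep(1 / 3, 3))
  w2 <- sequence_weights(encode_msa(msa(c("AAAA", "CCCC", "GGGG"))))
  expect_equal(w2, rep(1, 3))
  # frozen from the brute-force pairwise identity oracle:
  # {q,s1}=.8 {q,s2}=.6 {q,s3}=1 {s1,s2}=.8 {s1,s3}=.8 {s2,s3}=.6
  m <- msa(c("ACDEF", "ACDEG", "ACDGG", "ACDEF"))
  w <- sequence_weights(encode_msa(m), theta = 0.8)
  expect_equal(w, c(1 / 3, 1 / 4, 1 / 2, 1 / 3))
  expect_equal(w, oracle_weights(oracle_char_matrix(m$seqs), 0.8))
})

test_that("compute_neff applies the normalization options to the weight sum", {
  m <- msa(c("ACDEF", "ACDEG", "ACDGG", "ACDEF"))
  r <- compute_neff(m, norm = "none")
  expect_equal(r$raw_sum, 17 / 12)
  expect_equal(r$neff, 17 / 12)
  expect_equal(compute_neff(m, norm = "by_length")$neff, (17 / 12) / 5)
  expect_equal(compute_neff(m, norm = "by_sqrt_length")$neff, (17 / 12) / sqrt(5))
  # k identical ungapped copies have unit effective size for any k
  for (k in c(1, 2, 10, 100))
    expect_equal(compute_neff(msa(rep("ACDEFGHIKL", k)), norm = "none")$neff, 1.0)
})

test_that("duplicating every row leaves the unnormalized NEFF unchanged", {
  set.seed(42)
  for (rep in 1:5) {
    m <- rand_msa(8, 20, gap_p = 0.15)
    r1 <- compute_neff(m, norm = "none")
    m2 <- msa(c(m$seqs, m$seqs))
    r2 <- compute_neff(m2, norm = "none")
    expect_equal(r2$neff, r1$neff, tolerance = 1e-9)
  }
})

test_that("row order does not affect the result when the query is tracked", {
  set.seed(43)
  m <- rand_msa(10, 18, gap_p = 0.15)
  r1 <- compute_neff(m, norm = "none")
  perm <- sample(10)
  mp <- msa(m$seqs[perm], ids = m$ids[perm], query_index = match(1L, perm))
  r2 <- compute_neff(mp, norm = "none")
  expect_equal(r2$neff, r1$neff)
  expect_equal(r2$weights[names(r1$weights)], r1$weights)
})

test_that("NEFF is monotone in theta and bounded by [1, N]", {
  set.seed(44)
  thetas <- seq(0.1, 1, by = 0.1)
  for (rep in 1:5) {
    m <- rand_msa(12, 20, gap_p = 0.1)
    vals <- vapply(thetas, function(th)
      compute_neff(m, theta = th, norm = "none")$neff, numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
    expect_true(all(vals >= 1 - 1e-12 & vals <= 12 + 1e-12))
  }
})

test_that("A3M input is resolved to match columns before computing", {
  a3 <- msa(c("ACDEF", "ACgDEF"), format = "a3m")
  r <- compute_neff(a3, norm = "none")
  expect_equal(r$n_cols, 5L)
  expect_equal(r$neff, compute_neff(msa(c("ACDEF", "ACDEF")), norm = "none")$neff)
})

test_that("per-residue values sum sequence weights at residue positions", {
  m <- msa(c("ACDEF", "ACDEG", "ACDGG", "ACDEF"))
  pr <- per_residue_neff(m)
  r <- compute_neff(m, norm = "none")
  # gap-free: every column equals the raw weight sum
  expect_equal(unname(as.numeric(pr)), rep(r$raw_sum, 5))
  expect_equal(attr(pr, "raw_sum"), r$raw_sum)

  # s2's last column changed to a gap: column 5 = raw_sum - weight(s2),
  # with the weights recomputed on the modified MSA
  m2 <- msa(c("ACDEF", "ACDEG", "ACDG-", "ACDEF"))
  r2 <- compute_neff(m2, norm = "none")
  pr2 <- per_residue_neff(m2)
  expect_equal(unname(pr2["5"]), r2$raw_sum - unname(r2$weights[3]))
  expect_equal(unname(as.numeric(pr2)), oracle_per_residue(m2$seqs))

  # column where only the query is non-gap
  m3 <- msa(c("ACDEF", "ACDE-", "ACDE-"))
  pr3 <- per_residue_neff(m3)
  r3 <- compute_neff(m3, norm = "none")
  expect_equal(unname(pr3["5"]), unname(r3$weights[1]))
})

test_that("per-residue values are indexed by original column coordinates", {
  m <- msa(c("A-CD", "AGCD", "AGC-"))
  pr <- per_residue_neff(m)
  expect_equal(names(pr), c("1", "3", "4"))
  expect_true(all(pr <= attr(pr, "raw_sum") + 1e-12))
  # normalization options apply on request
  prn <- per_residue_neff(m, norm = "by_length")
  expect_equal(unname(as.numeric(prn)), unname(as.numeric(pr)) / 3)
})

test_that("optimized weights equal the naive double loop on random MSAs", {
  set.seed(45)
  for (rep in 1:20) {
    n <- sample(2:30, 1); L <- sample(5:30, 1)
    ab <- sample(c("protein", "dna", "rna"), 1)
    theta <- sample(c(0.5, 0.62, 0.8, 1.0), 1)
    sym <- sample(c(TRUE, FALSE), 1)
    m <- rand_msa(n, L, alphabet = ab, gap_p = 0.2, nonstd_p = 0.05)
    policy <- sample(c("as_standard", "as_gap"), 1)
    enc <- encode_msa(m, ab, non_standard = policy)
    w <- suppressMessages(sequence_weights(enc, theta, sym))
    gap_syms <- if (policy == "as_gap") ORACLE_NONSTD[[ab]] else character()
    ow <- oracle_weights(oracle_char_matrix(m$seqs, gap_syms), theta, sym)
    expect_identical(w, ow)
  }
})

test_that("invalid options are rejected", {
  expect_error(neff_options(theta = 0), class = "neffr_option_error")
  expect_error(neff_options(theta = 1.2), class = "neffr_option_error")
  expect_error(neff_options(gap_cutoff = 0), class = "neffr_option_error")
  expect_error(neff_options(depth = 0), class = "neffr_option_error")
})
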