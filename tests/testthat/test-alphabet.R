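test_that("alphabet symbol sets are pairwise disjoint and complete", {
  for (name in c("protein", "dna", "rna")) {
    ab <- msa_alphabet(name)
    expect_length(intersect(ab$standard, ab$non_standard), 0)
    expect_length(intersect(ab$standard, ab$gaps), 0)
    expect_length(intersect(ab$non_standard, ab$gaps), 0)
  }
  expect_length(msa_alphabet("protein")$standard, 20)
  expect_setequal(msa_alphabet("dna")$standard, c("A", "C", "G", "T"))
  expect_setequal(msa_alphabet("rna")$standard, c("A", "C", "G", "U"))
})

test_that("encoding folds case, maps both gap characters, and honors the policy", {
  m <- msa(c("AC-a", "ac.A"))
  enc <- encode_msa(m, "protein")
  sm <- enc$symbol_map
  expect_equal(enc$matrix[1, ], unname(c(sm["A"], sm["C"], 0L, sm["A"])))
  expect_equal(enc$matrix[2, ], unname(c(sm["A"], sm["C"], 0L, sm["A"])))
  expect_equal(enc$gap_code, 0L)

  asg <- encode_msa(msa("AXC"), "protein", non_standard = "as_gap")
  expect_equal(asg$matrix[1, 2], 0L)
  ast <- encode_msa(msa("AXC"), "protein", non_standard = "as_standard")
  expect_gt(ast$matrix[1, 2], 0L)
  expect_false(ast$matrix[1, 2] %in% ast$matrix[1, c(1, 3)])
})

test_that("characters outside the alphabet are rejected with location info", {
  err <- expect_error(encode_msa(msa("ACGU", ids = "r1"), "dna"),
                      class = "neffr_encoding_error")
  expect_match(conditionMessage(err), "'U'")
  expect_match(conditionMessage(err), "r1")
  expect_match(conditionMessage(err), "column 4")
  expect_error(encode_msa(msa("AC*D"), "protein"),
               class = "neffr_encoding_error")
})

test_that("decode inverts encode up to case and gap normalization", {
  set.seed(11)
  for (ab in c("protein", "dna", "rna")) {
    m <- rand_msa(8, 15, alphabet = ab, gap_p = 0.2, nonstd_p = 0.1)
    m$seqs[2] <- tolower(m$seqs[2])
    m$seqs[3] <- chartr("-", ".", m$seqs[3])
    enc <- encode_msa(m, ab, non_standard = "as_standard")
    expect_equal(unname(decode_msa(enc)),
                 toupper(chartr(".", "-", m$seqs)))
  }
})

test_that("as_gap never decreases the per-row gap-code count", {
  set.seed(12)
  for (rep in 1:10) {
    m <- rand_msa(6, 20, gap_p = 0.2, nonstd_p = 0.15)
    g_std <- rowSums(encode_msa(m, non_standard = "as_standard")$matrix == 0L)
    g_gap <- rowSums(encode_msa(m, non_standard = "as_gap")$matrix == 0L)
    expect_true(all(g_gap >= g_std))
  }
})
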