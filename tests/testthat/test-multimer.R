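test_that("segmentation classifies rows and builds chain sub-MSAs", {
  m <- msa(c("ACDACD", "ACD---", "AC-AC-"), ids = c("q", "u1", "p1"))
  seg <- segment_multimer(m, multimer_spec(c(3, 3)))
  expect_equal(seg$row_classes, c("query", "unpaired(1)", "paired"))
  expect_equal(seg$chains[[1]]$seqs, c("ACD", "ACD", "AC-"))
  expect_equal(seg$chains[[1]]$ids, c("q", "u1", "p1"))
  expect_equal(seg$chains[[2]]$seqs, c("ACD", "AC-"))
  expect_equal(seg$chains[[2]]$ids, c("q", "p1"))
  expect_equal(seg$paired_rows, 3L)
  # column conservation
  expect_equal(sum(vapply(seg$chains, function(ch) nchar(ch$seqs[1]), integer(1))),
               6L)
})

test_that("spec errors are raised for inconsistent layouts", {
  m <- msa(c("ACDACD", "ACDACD"))
  expect_error(segment_multimer(m, multimer_spec(c(3, 4))),
               class = "neffr_spec_error")
  mq <- msa(c("ACD---", "ACDACD"))
  expect_error(segment_multimer(mq, multimer_spec(c(3, 3))),
               class = "neffr_spec_error")
  expect_error(multimer_spec(c(3, 0)), class = "neffr_spec_error")
})

test_that("rows with no residues anywhere are dropped with a warning", {
  m <- msa(c("ACDACD", "------", "ACDAC-"))
  expect_warning(seg <- segment_multimer(m, multimer_spec(c(3, 3))), "dropped")
  expect_equal(seg$row_classes[2], "dropped")
  res <- suppressWarnings(
    compute_multimer_neff(m, multimer_spec(c(3, 3)), neff_options(norm = "none")))
  expect_equal(res$overall$n_rows, 2L)
})

test_that("a single-chain spec degrades to the standard computation", {
  set.seed(51)
  m <- rand_msa(8, 12, gap_p = 0.1)
  opt <- neff_options(norm = "none")
  std <- compute_neff(m, opt)
  res <- compute_multimer_neff(m, multimer_spec(12L), opt)
  expect_equal(res$overall$neff, std$neff)
  expect_equal(res$per_chain[[1]]$neff, std$neff)
  expect_equal(sum(res$row_classes == "paired"), 0L)
})

test_that("block NEFF values match naive recomputation on each block", {
  m <- msa(c("ACDACD", "ACD---", "AC-AC-"), ids = c("q", "u1", "p1"))
  opt <- neff_options(norm = "none")
  res <- compute_multimer_neff(m, multimer_spec(c(3, 3)), opt)
  expect_equal(res$overall$neff, oracle_neff(m$seqs, 0.8)$neff)
  expect_equal(res$paired$neff, oracle_neff(m$seqs[c(1, 3)], 0.8)$neff)
  expect_equal(res$per_chain[[1]]$neff,
               oracle_neff(c("ACD", "ACD", "AC-"), 0.8)$neff)
  expect_equal(res$per_chain[[2]]$neff,
               oracle_neff(c("ACD", "AC-"), 0.8)$neff)
})

test_that("homomer chain merging deduplicates identical sub-MSAs", {
  set.seed(52)
  half <- rand_msa(6, 10, gap_p = 0.1)
  m <- msa(paste0(half$seqs, half$seqs), ids = half$ids)
  opt <- neff_options(norm = "none")
  res <- compute_multimer_neff(m, multimer_spec(c(10, 10), "A2"), opt,
                               merge_homomer_chains = TRUE)
  expect_equal(res$merged_entity$neff, res$per_chain[[1]]$neff)
  expect_equal(res$merged_entity$n_rows, res$per_chain[[1]]$n_rows)
  # heteromer queries refuse the homomer merge
  het <- msa(c("ACDWWW", "ACDWW-"), ids = c("q", "s"))
  expect_error(
    compute_multimer_neff(het, multimer_spec(c(3, 3)), opt,
                          merge_homomer_chains = TRUE),
    class = "neffr_spec_error")
})

test_that("generated multimer fixtures reproduce their constructed classes", {
  for (pf in c(0, 0.5, 1)) {
    gen <- generate_multimer_msa(21, c(12, 9), paired_fraction = pf, seed = 53)
    seg <- segment_multimer(gen$msa, gen$spec)
    expect_equal(seg$row_classes, gen$classes)
    expect_equal(sum(seg$row_classes == "paired"), round(20 * pf))
  }
})
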