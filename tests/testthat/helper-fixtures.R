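# Random raw-character MSAs (query row kept gap-free so that default
# query-gap removal keeps at least one column).
rand_rows <- function(n, L, alphabet = "protein", gap_p = 0.15,
                      nonstd_p = 0) {
  ab <- msa_alphabet(alphabet)
  pool <- ab$standard
  rows <- vapply(seq_len(n), function(i) {
    cc <- sample(pool, L, replace = TRUE)
    if (nonstd_p > 0) {
      hit <- runif(L) < nonstd_p
      cc[hit] <- sample(ab$non_standard, sum(hit), replace = TRUE)
    }
    if (i > 1L && gap_p > 0) cc[runif(L) < gap_p] <- "-"
    paste(cc, collapse = "")
  }, character(1))
  rows
}

rand_msa <- function(n, L, ...) msa(rand_rows(n, L, ...))

expect_same_msa_seqs <- function(a, b) {
  expect_equal(toupper(chartr(".", "-", a$seqs)),
               toupper(chartr(".", "-", b$seqs)))
}

aligned_formats <- c("fasta", "sto", "aln", "clustal", "pfam")
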