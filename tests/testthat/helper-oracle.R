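# Literal naive reimplementation of the effective-sequence-count pipeline,
# working directly on character rows. Deliberately independent of the
# package's encoding and C++ kernel: this is the oracle the optimized path
# is checked against.

ORACLE_NONSTD <- list(
  protein = c("B", "J", "O", "U", "X", "Z"),
  dna = c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "X"),
  rna = c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "X"))

# rows -> character matrix, uppercased, '.' -> '-', optional symbols -> '-'
oracle_char_matrix <- function(rows, gap_syms = character()) {
  mat <- do.call(rbind, strsplit(chartr(".", "-", toupper(rows)), "", fixed = TRUE))
  mat[mat %in% gap_syms] <- "-"
  mat
}

oracle_preprocess <- function(mat, keep_query_gaps = FALSE, gap_cutoff = 1,
                              depth = NULL, query = 1L) {
  if (!is.null(depth) && depth < nrow(mat)) {
    keep <- seq_len(depth)
    if (!query %in% keep) keep <- c(seq_len(depth - 1L), query)
    mat <- mat[keep, , drop = FALSE]
  }
  if (!keep_query_gaps) mat <- mat[, mat[query, ] != "-", drop = FALSE]
  if (gap_cutoff < 1) {
    frac <- colMeans(mat == "-")
    mat <- mat[, !(frac > gap_cutoff), drop = FALSE]
  }
  mat
}

# O(N^2 L) double loop over ordered pairs; inclusive threshold.
oracle_weights <- function(mat, theta, symmetric = TRUE) {
  n <- nrow(mat); L <- ncol(mat)
  nn <- rep(1L, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- mat[i, ]; b <- mat[j, ]
    s <- if (symmetric) sum(a == b) / L
         else {
           ng <- sum(b != "-")
           if (ng == 0L) 0 else sum(a == b & b != "-") / ng
         }
    if (s >= theta) nn[j] <- nn[j] + 1L   # similarity *into* j
  }
  1 / nn
}

oracle_neff <- function(rows, theta = 0.8, symmetric = TRUE, norm = "none",
                        gap_cutoff = 1, keep_query_gaps = FALSE, depth = NULL,
                        gap_syms = character(), query = 1L) {
  mat <- oracle_char_matrix(rows, gap_syms)
  mat <- oracle_preprocess(mat, keep_query_gaps, gap_cutoff, depth, query)
  w <- oracle_weights(mat, theta, symmetric)
  s <- sum(w)
  L <- ncol(mat)
  list(weights = w, raw_sum = s, L = L,
       neff = s * switch(norm, none = 1, by_length = 1 / L,
                         by_sqrt_length = 1 / sqrt(L)))
}

oracle_per_residue <- function(rows, theta = 0.8, symmetric = TRUE,
                               gap_syms = character()) {
  mat <- oracle_char_matrix(rows, gap_syms)
  mat <- oracle_preprocess(mat)
  w <- oracle_weights(mat, theta, symmetric)
  colSums((mat != "-") * w)
}
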