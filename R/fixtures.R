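#' Generate a synthetic clustered alignment
#'
#' Deterministic generator used throughout the test suite and usable as a
#' benchmark source. A root sequence is drawn uniformly over the standard
#' alphabet; `n_clusters` cluster centers are derived from it by
#' substituting each column with probability `center_divergence`; each row
#' is assigned to a center (round-robin) and mutated per column at
#' `mutation_rate`, then gaps are injected per cell at `gap_rate`. The
#' query (row 1) is the unmutated, gap-free root, so with small
#' `mutation_rate` and `theta = 0.8` the unnormalized NEFF approaches
#' `n_clusters`. Output is reproducible for a fixed `seed` (Mersenne
#' Twister; the caller's RNG state is untouched).
#'
#' @param n_rows,n_cols Alignment dimensions (rows include the query).
#' @param alphabet [msa_alphabet] or its name.
#' @param mutation_rate Per-column substitution probability from the
#'   cluster center, in \[0, 1\]. Substitutions draw uniformly from the
#'   standard symbols (and may redraw the original).
#' @param gap_rate Per-cell gap probability in \[0, 1), never applied to
#'   the query.
#' @param n_clusters Number of identity clusters (must not exceed `n_rows`).
#' @param center_divergence Per-column substitution probability separating
#'   cluster centers from the root (default 0.5, keeping across-cluster
#'   identity well below the usual 0.8 threshold).
#' @param seed Integer seed.
#' @return An [msa] with ids `query, seq_2, ...`; the cluster assignment is
#'   attached as `attr(, "clusters")`.
#' @export
generate_msa <- function(n_rows, n_cols, alphabet = "protein",
                         mutation_rate = 0.05, gap_rate = 0,
                         n_clusters = 1L, center_divergence = 0.5,
                         seed = 1L) {
  alphabet <- as_alphabet(alphabet)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n_clusters <- as.integer(n_clusters)
  if (n_rows < 1L || n_cols < 1L) stop_neffr("n_rows and n_cols must be >= 1", "option")
  if (n_clusters < 1L || n_clusters > n_rows)
    stop_neffr("n_clusters must lie in [1, n_rows]", "option")
  if (mutation_rate < 0 || mutation_rate > 1 || gap_rate < 0 || gap_rate >= 1)
    stop_neffr("rates out of range", "option")
  syms <- alphabet$standard
  local_seed(seed, {
    root <- sample(syms, n_cols, replace = TRUE)
    centers <- lapply(seq_len(n_clusters), function(cl) {
      if (cl == 1L) return(root)
      mut <- stats::runif(n_cols) < center_divergence
      out <- root
      out[mut] <- sample(syms, sum(mut), replace = TRUE)
      out
    })
    assign_cluster <- c(1L, if (n_rows > 1L)
      rep_len(seq_len(n_clusters), n_rows - 1L))
    seqs <- character(n_rows)
    seqs[1] <- paste(root, collapse = "")
    for (i in seq_len(n_rows)[-1]) {
      row <- centers[[assign_cluster[i]]]
      mut <- stats::runif(n_cols) < mutation_rate
      row[mut] <- sample(syms, sum(mut), replace = TRUE)
      if (gap_rate > 0) row[stats::runif(n_cols) < gap_rate] <- "-"
      seqs[i] <- paste(row, collapse = "")
    }
    out <- msa(seqs, ids = c("query", if (n_rows > 1L)
      paste0("seq_", seq_len(n_rows)[-1])), format = "fasta")
    attr(out, "clusters") <- assign_cluster
    out
  })
}

#' Generate a synthetic concatenated multimer alignment
#'
#' Builds one clustered block per chain with [generate_msa()] and
#' concatenates them. The query spans all chains. Of the non-query rows, a
#' `paired_fraction` carry residues in every chain; the remainder occupy
#' exactly one chain (assigned round-robin) with gaps elsewhere.
#'
#' @param n_rows Total rows including the query.
#' @param chain_lengths Columns per chain.
#' @param paired_fraction Fraction of non-query rows paired, in \[0, 1\].
#' @param alphabet,mutation_rate,gap_rate,n_clusters,seed As in
#'   [generate_msa()].
#' @return List with `msa`, `spec` (a [multimer_spec]) and `classes` (the
#'   constructed row classification, same labels as [segment_multimer()]).
#' @export
generate_multimer_msa <- function(n_rows, chain_lengths, paired_fraction = 0.5,
                                  alphabet = "protein", mutation_rate = 0.05,
                                  gap_rate = 0, n_clusters = 1L, seed = 1L) {
  if (paired_fraction < 0 || paired_fraction > 1)
    stop_neffr("paired_fraction must lie in [0, 1]", "option")
  chain_lengths <- as.integer(chain_lengths)
  k <- length(chain_lengths)
  if (k < 1L) stop_neffr("need at least one chain", "option")
  blocks <- lapply(seq_len(k), function(ch)
    generate_msa(n_rows, chain_lengths[ch], alphabet = alphabet,
                 mutation_rate = mutation_rate, gap_rate = gap_rate,
                 n_clusters = n_clusters, seed = seed + ch))
  n_other <- n_rows - 1L
  n_paired <- as.integer(round(n_other * paired_fraction))
  classes <- "query"
  seqs <- paste0(vapply(blocks, function(b) b$seqs[1], character(1)),
                 collapse = "")
  if (n_other > 0L) {
    chain_of <- rep_len(seq_len(k), n_other)  # for unpaired rows
    for (i in seq_len(n_other)) {
      row_i <- i + 1L
      if (i <= n_paired) {
        classes <- c(classes, "paired")
        seqs <- c(seqs, paste0(vapply(blocks, function(b) b$seqs[row_i],
                                      character(1)), collapse = ""))
      } else {
        ch <- chain_of[i]
        classes <- c(classes, sprintf("unpaired(%d)", ch))
        parts <- vapply(seq_len(k), function(cc)
          if (cc == ch) blocks[[cc]]$seqs[row_i]
          else strrep("-", chain_lengths[cc]), character(1))
        seqs <- c(seqs, paste0(parts, collapse = ""))
      }
    }
  }
  m <- msa(seqs, ids = c("query", if (n_other > 0L)
    paste0("seq_", seq_len(n_other) + 1L)), format = "fasta")
  list(msa = m, spec = multimer_spec(chain_lengths), classes = classes)
}
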