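#' Describe the chain layout of a concatenated multimer MSA
#'
#' Multimer alignments (the paired MSAs used by complex-structure
#' predictors) concatenate one aligned block per chain; chain boundaries
#' are given explicitly as column counts. An optional stoichiometry label
#' (e.g. `"A2"`, `"A1B1"`) is carried along for reporting.
#'
#' @param chain_lengths Positive integer vector of columns per chain; must
#'   sum to the MSA's aligned width.
#' @param stoichiometry Optional text label.
#' @return Object of class `multimer_spec`.
#' @export
multimer_spec <- function(chain_lengths, stoichiometry = NULL) {
  chain_lengths <- as.integer(chain_lengths)
  if (!length(chain_lengths) || any(is.na(chain_lengths)) ||
      any(chain_lengths < 1L))
    stop_neffr("chain_lengths must be positive integers", "spec")
  structure(list(chain_lengths = chain_lengths,
                 stoichiometry = stoichiometry),
            class = "multimer_spec")
}

#' Segment a multimer MSA into chain blocks and row classes
#'
#' Cuts every row at the cumulative chain boundaries. A non-query row is
#' `paired` iff at least two of its chain segments contain a residue,
#' otherwise `unpaired` for its single occupied chain; rows with no residue
#' anywhere are dropped with a warning. The query (row at `query_index`)
#' must carry residues in every chain. Chain *k*'s sub-MSA is the query's
#' segment plus, in row order, segment *k* of every row occupying chain
#' *k*.
#'
#' @param msa Column-aligned [msa] (or file path).
#' @param spec A [multimer_spec]; `sum(chain_lengths)` must equal the
#'   alignment width.
#' @return List with `row_classes` (character per input row: `"query"`,
#'   `"paired"`, `"unpaired(k)"`, or `"dropped"`), `chains` (list of [msa],
#'   one per chain) and `paired_rows` (indices).
#' @export
segment_multimer <- function(msa, spec) {
  msa <- as_msa(msa)
  stopifnot(inherits(spec, "multimer_spec"))
  if (!is_aligned(msa))
    stop_neffr("multimer segmentation needs a column-aligned MSA", "spec")
  L <- nchar(msa$seqs[1])
  if (sum(spec$chain_lengths) != L)
    stop_neffr(sprintf("chain lengths sum to %d but the MSA has %d columns",
                       sum(spec$chain_lengths), L), "spec")
  k <- length(spec$chain_lengths)
  ends <- cumsum(spec$chain_lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  segs <- lapply(seq_len(k), function(ch)
    substring(msa$seqs, starts[ch], ends[ch]))
  occupied <- do.call(cbind, lapply(seq_len(k), function(ch)
    grepl("[A-Za-z]", segs[[ch]])))

  q <- msa$query_index
  if (!all(occupied[q, ]))
    stop_neffr("the query row has an all-gap chain segment", "spec")
  n_occ <- rowSums(occupied)
  classes <- character(length(msa$seqs))
  classes[q] <- "query"
  for (i in seq_along(classes)) {
    if (i == q) next
    classes[i] <- if (n_occ[i] == 0L) "dropped"
      else if (n_occ[i] >= 2L) "paired"
      else sprintf("unpaired(%d)", which(occupied[i, ]))
  }
  if (any(classes == "dropped"))
    warning(sum(classes == "dropped"),
            " row(s) with no residues in any chain were dropped", call. = FALSE)

  chains <- lapply(seq_len(k), function(ch) {
    rows <- which(occupied[, ch] | seq_along(classes) == q)
    rows <- unique(c(q, setdiff(rows, q)))
    rows <- rows[order(rows != q, rows)]   # query first, then original order
    msa(segs[[ch]][rows], ids = msa$ids[rows], format = "fasta",
        query_index = 1L)
  })
  list(row_classes = classes, chains = chains,
       paired_rows = which(classes == "paired"))
}

#' NEFF of a multimer alignment, overall and per block
#'
#' Computes the effective-sequence count on (i) the full concatenated MSA,
#' (ii) the query plus the paired rows at full width, and (iii) each
#' chain's sub-MSA over the rows occupying that chain. For homomers (all
#' query chain segments identical), `merge_homomer_chains = TRUE`
#' additionally stacks the chain sub-MSAs, removes duplicate sequences and
#' reports a single per-entity NEFF. All component computations honor
#' `options`.
#'
#' @param msa Column-aligned [msa] or file path.
#' @param spec A [multimer_spec].
#' @param options A [neff_options].
#' @param merge_homomer_chains Logical.
#' @param ... Forwarded to [neff_options()] when `options` is missing.
#' @return Object of class `multimer_neff_result`: list with `overall`,
#'   `paired`, `per_chain` (list of [compute_neff()] results), `row_classes`,
#'   `spec`, and optionally `merged_entity`.
#' @export
compute_multimer_neff <- function(msa, spec, options = NULL,
                                  merge_homomer_chains = FALSE, ...) {
  if (is.null(options)) options <- neff_options(...)
  msa <- as_msa(msa)
  seg <- segment_multimer(msa, spec)
  keep <- seg$row_classes != "dropped"
  m_kept <- msa(msa$seqs[keep], ids = msa$ids[keep], format = "fasta",
                query_index = match(msa$query_index, which(keep)))
  overall <- compute_neff(m_kept, options)
  q <- msa$query_index
  prows <- sort(unique(c(q, seg$paired_rows)))
  paired_msa <- msa(msa$seqs[prows], ids = msa$ids[prows], format = "fasta",
                    query_index = match(q, prows))
  paired <- compute_neff(paired_msa, options)
  per_chain <- lapply(seg$chains, compute_neff, options = options)

  merged_entity <- NULL
  if (merge_homomer_chains) {
    qsegs <- vapply(seg$chains, function(ch) normalize_seq(ch$seqs[1]),
                    character(1))
    if (length(unique(qsegs)) != 1L)
      stop_neffr("merge_homomer_chains requires identical query segments in every chain (a homomer)",
                 "spec")
    merged <- merge_msas(seg$chains)
    merged_entity <- compute_neff(merged, options)
  }
  structure(list(overall = overall, paired = paired, per_chain = per_chain,
                 merged_entity = merged_entity, row_classes = seg$row_classes,
                 spec = spec),
            class = "multimer_neff_result")
}

#' @export
print.multimer_neff_result <- function(x, ...) {
  lab <- x$spec$stoichiometry
  cat("Multimer NEFF",
      if (!is.null(lab)) paste0(" (", lab, ")"), "\n", sep = "")
  cat(sprintf("  overall (%d chains, %d rows): %.6g\n",
              length(x$spec$chain_lengths), x$overall$n_rows, x$overall$neff))
  cat(sprintf("  paired rows (%d): %.6g\n", x$paired$n_rows, x$paired$neff))
  for (k in seq_along(x$per_chain))
    cat(sprintf("  chain %d (%d cols, %d rows): %.6g\n", k,
                x$spec$chain_lengths[k], x$per_chain[[k]]$n_rows,
                x$per_chain[[k]]$neff))
  if (!is.null(x$merged_entity))
    cat(sprintf("  merged homomer entity: %.6g\n", x$merged_entity$neff))
  tab <- table(sub("\\(.*", "", x$row_classes))
  cat("  row classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
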