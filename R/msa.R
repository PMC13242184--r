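#' Construct a multiple sequence alignment object
#'
#' The in-memory MSA container: ordered records (id, optional description,
#' aligned sequence), the source format, passthrough annotation lines
#' (Stockholm `#=GF/#=GC/#=GS/#=GR`), and the query row index. The query is
#' the sequence the alignment was built for; by convention it is the first
#' record. Sequences may contain `-`, `.` and mixed case as the source
#' format dictates; A2M/A3M rows are stored verbatim and become
#' column-aligned through [resolve_insertions()].
#'
#' @param seqs Character vector of aligned sequences.
#' @param ids Character vector of record ids (defaults to `seq_1 ...`).
#' @param desc Optional character vector of descriptions.
#' @param format Source format, one of [msa_formats()].
#' @param annotations Character vector of verbatim annotation lines.
#' @param query_index 1-based index of the query row (default 1).
#' @return An object of class `msa`.
#' @examples
#' m <- msa(c("ACDEF", "ACDEG"), ids = c("query", "hit1"))
#' m
#' @export
msa <- function(seqs, ids = NULL, desc = NULL, format = "fasta",
                annotations = character(), query_index = 1L) {
  seqs <- as.character(seqs)
  if (length(seqs) < 1L) stop_neffr("an MSA needs at least one record", "parse")
  if (any(!nzchar(seqs))) stop_neffr("empty sequence in MSA", "parse")
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  ids <- as.character(ids)
  if (length(ids) != length(seqs) || any(!nzchar(ids)))
    stop_neffr("every record needs a non-empty id", "parse")
  if (is.null(desc)) desc <- rep("", length(seqs))
  query_index <- as.integer(query_index)
  if (query_index < 1L || query_index > length(seqs))
    stop_neffr("query_index out of range", "option")
  if (!format %in% msa_formats())
    stop_neffr(paste0("unknown MSA format '", format, "'"), "option")
  structure(list(ids = ids, desc = as.character(desc), seqs = seqs,
                 source_format = format, annotations = as.character(annotations),
                 query_index = query_index),
            class = "msa")
}

as_msa <- function(x, format = NULL) {
  if (inherits(x, "msa")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_msa(x, format = format))
  stop_neffr("expected an 'msa' object or a file path", "option")
}

#' Supported alignment formats
#' @return Character vector of the seven supported format names.
#' @export
msa_formats <- function() c("fasta", "a2m", "a3m", "sto", "aln", "clustal", "pfam")

#' Number of records in an MSA
#' @param x An `msa`.
#' @export
n_records <- function(x) length(as_msa(x)$seqs)

# TRUE when all rows have equal length (the column-aligned case).
is_aligned <- function(msa) length(unique(nchar(msa$seqs))) == 1L

# uppercase, '.'-to-'-' normalized sequence string (dedupe / comparison key)
normalize_seq <- function(s) chartr(".", "-", toupper(s))

#' @export
print.msa <- function(x, ...) {
  L <- unique(nchar(x$seqs))
  cat(sprintf("<msa> %d records, %s columns (%s format)\n",
              length(x$seqs),
              if (length(L) == 1L) L else paste0(min(L), "-", max(L), " raw"),
              x$source_format))
  cat(sprintf("  query: [%d] %s\n", x$query_index, x$ids[x$query_index]))
  show <- utils::head(seq_along(x$seqs), 5L)
  for (i in show) {
    s <- x$seqs[i]
    if (nchar(s) > 50L) s <- paste0(substr(s, 1L, 50L), "...")
    cat(sprintf("  %-12s %s\n", substr(x$ids[i], 1L, 12L), s))
  }
  if (length(x$seqs) > 5L) cat("  ...", length(x$seqs) - 5L, "more\n")
  if (length(x$annotations))
    cat("  +", length(x$annotations), "annotation line(s)\n")
  invisible(x)
}
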