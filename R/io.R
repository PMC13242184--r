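#' Detect the format of an alignment source
#'
#' Uses structural cues: the `# STOCKHOLM` magic line, a leading `CLUSTAL`
#' header word, `>` headers (with lowercase letters or `.` distinguishing
#' A2M/A3M from plain FASTA), two-column `id sequence` lines (PFAM), or bare
#' sequence lines (ALN). The A3M-vs-FASTA ambiguity is resolved as FASTA
#' when all rows are uppercase and of equal length. Deterministic.
#'
#' @param source File path, text blob, or character vector of lines.
#' @return A format name, one of [msa_formats()].
#' @export
detect_format <- function(source) {
  lines <- source_lines(source)
  nb <- lines[nzchar(trimws(lines))]
  if (!length(nb)) stop_neffr("empty source: cannot detect format", "parse")
  first <- trimws(nb[1])
  if (startsWith(first, "# STOCKHOLM")) return("sto")
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) return("clustal")
  if (startsWith(first, ">")) {
    seq_lines <- nb[!startsWith(trimws(nb), ">")]
    if (!length(seq_lines))
      stop_neffr("headers without sequences: unrecognized format", "parse")
    if (any(grepl(".", seq_lines, fixed = TRUE))) return("a2m")
    if (any(grepl("[a-z]", seq_lines))) return("a3m")
    return("fasta")
  }
  body <- nb[!startsWith(trimws(nb), "#") & trimws(nb) != "//"]
  if (!length(body)) stop_neffr("no sequence content: unrecognized format", "parse")
  fields <- strsplit(trimws(body), "[ \t]+")
  nf <- lengths(fields)
  seqish <- function(s) grepl("^[A-Za-z.*-]+$", s)
  if (all(nf == 2L) && all(vapply(fields, function(f) seqish(f[2]), logical(1))))
    return("pfam")
  if (all(nf == 1L) && all(vapply(fields, function(f) seqish(f[1]), logical(1))))
    return("aln")
  stop_neffr(
    "unrecognized MSA format; pass the format explicitly (e.g. format = 'fasta')",
    "parse")
}

parse_fasta_family <- function(lines, format) {
  ids <- character(); desc <- character(); seqs <- character()
  cur <- NULL; nseq <- 0L
  for (k in seq_along(lines)) {
    line <- lines[k]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      header <- sub("^>", "", trimws(line))
      id <- sub("[ \t].*$", "", header)
      if (!nzchar(id))
        stop_neffr(paste0("empty record id at line ", k), "parse")
      nseq <- nseq + 1L
      ids[nseq] <- id
      desc[nseq] <- if (grepl("[ \t]", header)) sub("^[^ \t]+[ \t]+", "", header) else ""
      seqs[nseq] <- ""
    } else {
      if (nseq == 0L)
        stop_neffr(paste0("sequence data before first '>' header at line ", k), "parse")
      seqs[nseq] <- paste0(seqs[nseq], gsub("[ \t]", "", line))
    }
  }
  if (nseq == 0L) stop_neffr("no records found", "parse")
  if (any(!nzchar(seqs))) {
    bad <- ids[which(!nzchar(seqs))[1]]
    stop_neffr(paste0("record '", bad, "' has no sequence"), "parse")
  }
  msa(seqs, ids = ids, desc = desc, format = format)
}

parse_sto <- function(lines, format = "sto") {
  nbidx <- which(nzchar(trimws(lines)))
  if (!length(nbidx)) stop_neffr("empty Stockholm source", "parse")
  if (format == "sto" && !startsWith(trimws(lines[nbidx[1]]), "# STOCKHOLM"))
    stop_neffr(paste0("missing '# STOCKHOLM' header at line ", nbidx[1]), "parse")
  if (format == "sto" && !any(trimws(lines) == "//"))
    stop_neffr("missing '//' terminator", "parse")
  ids <- character(); seqs <- list(); ann <- character()
  for (k in seq_along(lines)) {
    line <- lines[k]
    t <- trimws(line)
    if (!nzchar(t)) next
    if (t == "//") break
    if (startsWith(t, "#")) {
      if (startsWith(t, "#=")) ann <- c(ann, line)
      next
    }
    f <- strsplit(t, "[ \t]+")[[1]]
    if (length(f) != 2L)
      stop_neffr(paste0("expected 'id sequence' at line ", k), "parse")
    i <- match(f[1], ids)
    if (is.na(i)) { ids <- c(ids, f[1]); seqs[[length(ids)]] <- f[2] }
    else seqs[[i]] <- c(seqs[[i]], f[2])
  }
  if (!length(ids)) stop_neffr("no sequence records in Stockholm source", "parse")
  nchunk <- lengths(seqs)
  if (length(unique(nchunk)) != 1L)
    stop_neffr("ids appear in an inconsistent number of blocks", "parse")
  full <- vapply(seqs, paste, character(1), collapse = "")
  if (length(unique(nchar(full))) != 1L)
    stop_neffr("concatenated block lengths differ across ids", "parse")
  msa(full, ids = ids, format = format, annotations = ann)
}

parse_clustal <- function(lines) {
  nbidx <- which(nzchar(trimws(lines)))
  if (!length(nbidx)) stop_neffr("empty Clustal source", "parse")
  if (!grepl("^CLUSTAL", trimws(lines[nbidx[1]]), ignore.case = TRUE))
    stop_neffr("missing CLUSTAL header line", "parse")
  ids <- character(); seqs <- list()
  for (k in seq_along(lines)) {
    if (k == nbidx[1]) next
    line <- lines[k]
    if (!nzchar(trimws(line))) next
    if (grepl("^[ \t]", line)) next            # conservation line
    f <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(f) < 2L)
      stop_neffr(paste0("expected 'id chunk' at line ", k), "parse")
    i <- match(f[1], ids)
    if (is.na(i)) { ids <- c(ids, f[1]); seqs[[length(ids)]] <- f[2] }
    else seqs[[i]] <- c(seqs[[i]], f[2])
  }
  if (!length(ids)) stop_neffr("no sequence records in Clustal source", "parse")
  full <- vapply(seqs, paste, character(1), collapse = "")
  msa(full, ids = ids, format = "clustal")
}

parse_pfam <- function(lines) {
  ids <- character(); seqs <- character(); ann <- character()
  for (k in seq_along(lines)) {
    t <- trimws(lines[k])
    if (!nzchar(t) || t == "//") next
    if (startsWith(t, "#")) {
      if (startsWith(t, "#=")) ann <- c(ann, lines[k])
      next
    }
    f <- strsplit(t, "[ \t]+")[[1]]
    if (length(f) != 2L)
      stop_neffr(paste0("expected one 'id sequence' pair at line ", k), "parse")
    if (f[1] %in% ids)
      stop_neffr(paste0("duplicate id '", f[1], "' at line ", k), "parse")
    ids <- c(ids, f[1]); seqs <- c(seqs, f[2])
  }
  if (!length(ids)) stop_neffr("no records in PFAM source", "parse")
  msa(seqs, ids = ids, format = "pfam", annotations = ann)
}

parse_aln <- function(lines) {
  seqs <- trimws(lines)
  seqs <- seqs[nzchar(seqs)]
  if (!length(seqs)) stop_neffr("no rows in ALN source", "parse")
  bad <- which(!grepl("^[A-Za-z.*-]+$", seqs))
  if (length(bad))
    stop_neffr(paste0("non-sequence content in ALN row ", bad[1]), "parse")
  msa(seqs, ids = paste0("seq_", seq_along(seqs)), format = "aln")
}

#' Read a multiple sequence alignment
#'
#' Parses any of the seven supported formats into an [msa]. Record order is
#' preserved. FASTA/A2M/A3M wrap lines are concatenated; Stockholm
#' multi-block bodies are concatenated per id and `#=` annotation lines kept;
#' Clustal conservation lines are skipped; PFAM is one `id sequence` line
#' per record; ALN rows get synthesized ids `seq_1 ... seq_N`. A3M/A2M rows
#' are kept verbatim (use [resolve_insertions()] for a column-aligned view).
#'
#' @param source File path, text blob, or character vector of lines.
#' @param format A format name, or `NULL` to auto-detect.
#' @return An [msa].
#' @export
read_msa <- function(source, format = NULL) {
  lines <- source_lines(source)
  format <- format %||% detect_format(lines)
  if (!format %in% msa_formats())
    stop_neffr(paste0("unknown MSA format '", format, "'"), "option")
  switch(format,
    fasta = parse_fasta_family(lines, "fasta"),
    a2m   = parse_fasta_family(lines, "a2m"),
    a3m   = parse_fasta_family(lines, "a3m"),
    sto   = parse_sto(lines),
    clustal = parse_clustal(lines),
    pfam  = parse_pfam(lines),
    aln   = parse_aln(lines))
}

#' Resolve A2M/A3M insertion states into a column-aligned MSA
#'
#' In A2M/A3M, uppercase letters and `-` are match states; lowercase letters
#' and `.` are insertion states (A3M simply omits the `.` placeholders, so
#' raw row lengths differ). `mode = "remove"` deletes all insertion
#' characters, leaving the match columns; `mode = "expand"` turns every
#' insertion run into full alignment columns, with the inserting row
#' contributing its residues (uppercased) and all other rows `-`, runs
#' between the same match columns being left-aligned and padded. Match
#' columns are untouched in both modes.
#'
#' @param msa An [msa] read from an `a2m` or `a3m` source.
#' @param mode `"remove"` (default) or `"expand"`.
#' @return A column-aligned [msa] (FASTA-like).
#' @export
resolve_insertions <- function(msa, mode = c("remove", "expand")) {
  mode <- match.arg(mode)
  msa <- as_msa(msa)
  if (!msa$source_format %in% c("a2m", "a3m"))
    stop_neffr("resolve_insertions applies to a2m/a3m alignments only", "option")
  chars <- strsplit(msa$seqs, "", fixed = TRUE)
  is_match <- lapply(chars, function(cc) cc %in% c(LETTERS, "-") & cc != ".")
  nmatch <- vapply(is_match, sum, integer(1))
  if (length(unique(nmatch)) != 1L)
    stop_neffr(sprintf(
      "inconsistent A2M/A3M: match-column counts differ across rows (%s)",
      paste(unique(nmatch), collapse = ", ")), "parse")
  M <- nmatch[1]
  if (mode == "remove") {
    out <- vapply(seq_along(chars), function(i)
      paste(chars[[i]][is_match[[i]]], collapse = ""), character(1))
  } else {
    # per row: the insertion string in each of the M+1 slots between matches
    slot_ins <- lapply(seq_along(chars), function(i) {
      cc <- chars[[i]]; m <- is_match[[i]]
      ins <- vector("list", M + 1L)
      slot <- 1L; buf <- character()
      for (ch in seq_along(cc)) {
        if (m[ch]) { ins[[slot]] <- buf; buf <- character(); slot <- slot + 1L }
        else if (cc[ch] != ".") buf <- c(buf, toupper(cc[ch]))
      }
      ins[[slot]] <- buf
      for (s in seq_len(M + 1L)) if (is.null(ins[[s]])) ins[[s]] <- character()
      ins
    })
    widths <- vapply(seq_len(M + 1L), function(s)
      max(vapply(slot_ins, function(ins) length(ins[[s]]), integer(1))), integer(1))
    out <- vapply(seq_along(chars), function(i) {
      cc <- chars[[i]]; m <- is_match[[i]]; ins <- slot_ins[[i]]
      matches <- cc[m]
      parts <- character(0)
      for (s in seq_len(M)) {
        pad <- c(ins[[s]], rep("-", widths[s] - length(ins[[s]])))
        parts <- c(parts, pad, matches[s])
      }
      pad <- c(ins[[M + 1L]], rep("-", widths[M + 1L] - length(ins[[M + 1L]])))
      paste(c(parts, pad), collapse = "")
    }, character(1))
  }
  msa(out, ids = msa$ids, desc = msa$desc, format = "fasta",
      annotations = msa$annotations, query_index = msa$query_index)
}

wrap_seq <- function(s, width) {
  if (width <= 0L || nchar(s) <= width) return(s)
  starts <- seq(1L, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1L, nchar(s)))
}

#' Write a multiple sequence alignment
#'
#' Emits `msa` in any supported format such that [read_msa()] recovers the
#' same ids and ordered sequences (after the format's case/gap
#' normalization). FASTA/A2M/A3M wrap at `width` (default 60); Clustal is
#' written in 60-column blocks with padded ids; Stockholm carries the
#' annotation lines. Lossy targets warn about what they drop (ALN drops
#' ids; formats other than Stockholm/PFAM drop annotations).
#'
#' @param msa An [msa] (or file path).
#' @param path Output file path, or `NULL` to return the lines only.
#' @param format Target format (default: the MSA's source format).
#' @param width Wrap width for FASTA-family output.
#' @return Invisibly, the character vector of emitted lines.
#' @export
write_msa <- function(msa, path = NULL, format = NULL, width = 60L) {
  msa <- as_msa(msa)
  format <- format %||% msa$source_format
  if (!format %in% msa_formats())
    stop_neffr(paste0("unknown MSA format '", format, "'"), "option")
  if (!format %in% c("a2m", "a3m") && !is_aligned(msa))
    stop_neffr(paste0("'", format, "' requires a column-aligned MSA; ",
                      "run resolve_insertions() first"), "option")
  ann <- msa$annotations
  if (length(ann) && !format %in% c("sto", "pfam"))
    warning("format '", format, "' cannot carry annotations; dropping ",
            length(ann), " annotation line(s)", call. = FALSE)
  if (format == "aln" )
    warning("format 'aln' cannot carry record ids; dropping ids", call. = FALSE)

  lines <- switch(format,
    fasta = , a2m = , a3m = {
      unlist(lapply(seq_along(msa$seqs), function(i) {
        hdr <- paste0(">", msa$ids[i],
                      if (nzchar(msa$desc[i])) paste0(" ", msa$desc[i]) else "")
        c(hdr, wrap_seq(msa$seqs[i], width))
      }), use.names = FALSE)
    },
    sto = {
      pad <- max(nchar(msa$ids)) + 2L
      pre  <- ann[grepl("^#=G[FS]", trimws(ann))]
      post <- ann[!grepl("^#=G[FS]", trimws(ann))]
      c("# STOCKHOLM 1.0", "", pre,
        sprintf("%-*s%s", pad, msa$ids, msa$seqs),
        post, "//")
    },
    aln = msa$seqs,
    clustal = {
      pad <- max(nchar(msa$ids)) + 4L
      L <- nchar(msa$seqs[1])
      starts <- seq(1L, L, by = 60L)
      blocks <- lapply(starts, function(s) {
        chunk <- substring(msa$seqs, s, pmin(s + 59L, L))
        c(sprintf("%-*s%s", pad, msa$ids, chunk), "")
      })
      c("CLUSTAL multiple sequence alignment", "",
        unlist(blocks, use.names = FALSE))
    },
    pfam = {
      pad <- max(nchar(msa$ids)) + 2L
      c(ann, sprintf("%-*s%s", pad, msa$ids, msa$seqs))
    })
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Convert an alignment file between formats
#'
#' Reads `in_path`, resolves A2M/A3M insertion states when the target format
#' needs a column-aligned view (`insertion_mode` selects how), and writes
#' `out_path`. Sequence order is preserved and output is byte-deterministic
#' for fixed input and options.
#'
#' @param in_path Input file.
#' @param out_path Output file.
#' @param in_format Input format or `NULL` to auto-detect.
#' @param out_format Target format.
#' @param insertion_mode `"remove"` (default) or `"expand"`.
#' @param width Wrap width for FASTA-family output.
#' @return Invisibly, `out_path`.
#' @export
convert_msa <- function(in_path, out_path, out_format, in_format = NULL,
                        insertion_mode = c("remove", "expand"), width = 60L) {
  insertion_mode <- match.arg(insertion_mode)
  m <- read_msa(in_path, format = in_format)
  if (m$source_format %in% c("a2m", "a3m") && !out_format %in% c("a2m", "a3m"))
    m <- resolve_insertions(m, mode = insertion_mode)
  write_msa(m, path = out_path, format = out_format, width = width)
  invisible(out_path)
}

#' Merge multiple alignments sharing a query
#'
#' Concatenates the records of several column-aligned MSAs of identical
#' width in the given order and removes duplicate sequences: a record is a
#' duplicate iff its gap-normalized, uppercased sequence string equals that
#' of an earlier record (ids are ignored; the first occurrence wins). The
#' query of the first MSA becomes the merged query. By default all inputs
#' must share the same query sequence string.
#'
#' @param msas List of [msa] objects or file paths.
#' @param require_same_query Enforce an identical query across inputs.
#' @return A merged [msa]; the number of duplicates removed is available as
#'   `attr(, "duplicates_removed")`.
#' @export
merge_msas <- function(msas, require_same_query = TRUE) {
  if (inherits(msas, "msa")) msas <- list(msas)
  if (!length(msas)) stop_neffr("merge needs at least one MSA", "option")
  msas <- lapply(msas, as_msa)
  Ls <- vapply(msas, function(m) {
    if (!is_aligned(m))
      stop_neffr("merge requires column-aligned MSAs; resolve insertions first",
                 "merge")
    nchar(m$seqs[1])
  }, integer(1))
  if (length(unique(Ls)) != 1L)
    stop_neffr(paste0("cannot merge MSAs of different widths: ",
                      paste(Ls, collapse = ", ")), "merge")
  queries <- vapply(msas, function(m) normalize_seq(m$seqs[m$query_index]),
                    character(1))
  if (require_same_query && length(unique(queries)) != 1L)
    stop_neffr("inputs do not share the same query sequence (set require_same_query = FALSE to override)",
               "merge")
  ids <- unlist(lapply(msas, `[[`, "ids"), use.names = FALSE)
  desc <- unlist(lapply(msas, `[[`, "desc"), use.names = FALSE)
  seqs <- unlist(lapply(msas, `[[`, "seqs"), use.names = FALSE)
  ann <- unlist(lapply(msas, `[[`, "annotations"), use.names = FALSE)
  keep <- !duplicated(normalize_seq(seqs))
  qpos <- match(queries[1], normalize_seq(seqs[keep]))
  out <- msa(seqs[keep], ids = ids[keep], desc = desc[keep],
             format = msas[[1]]$source_format, annotations = ann,
             query_index = qpos)
  attr(out, "duplicates_removed") <- sum(!keep)
  out
}
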