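new_issue <- function(severity, line, message) {
  data.frame(severity = severity, line = if (is.null(line)) NA_integer_ else line,
             message = message, stringsAsFactors = FALSE)
}

# characters a format/alphabet combination accepts inside sequence fields
allowed_chars <- function(alphabet) {
  up <- c(alphabet$standard, alphabet$non_standard)
  c(up, tolower(up), "-", ".")
}

check_seq_chars <- function(seq, line, alphabet, issues) {
  cc <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(cc), allowed_chars(alphabet))
  if (length(bad)) {
    issues[[length(issues) + 1L]] <- new_issue(
      "error", line,
      sprintf("character(s) %s not permitted for alphabet '%s'",
              paste0("'", bad, "'", collapse = ", "), alphabet$name))
  }
  issues
}

check_equal_lengths <- function(lens, lines, what, issues) {
  if (length(lens) > 1L && length(unique(lens)) != 1L) {
    ref <- lens[1]
    off <- which(lens != ref)[1]
    issues[[length(issues) + 1L]] <- new_issue(
      "error", lines[off],
      sprintf("unequal %s length: %d (expected %d)", what, lens[off], ref))
  }
  issues
}

#' Validate an alignment file
#'
#' Checks that the source follows the declared format's structure (e.g.
#' Stockholm's magic header and `//` terminator, Clustal's header word,
#' FASTA's `>` records), that column-aligned formats have equal row
#' lengths (A3M: equal match-column counts), that every sequence character
#' belongs to the alphabet's standard/non-standard sets or is a gap, and
#' that the alignment is non-empty. The input is never modified. Unreadable
#' sources raise an I/O error rather than returning a report.
#'
#' @param source File path, text blob, or character vector of lines.
#' @param format One of [msa_formats()].
#' @param alphabet [msa_alphabet] or its name.
#' @return Object of class `msa_validation`: list with `ok` (TRUE iff no
#'   issue has severity `"error"`) and `issues` (data frame with columns
#'   `severity`, `line` — 1-based, NA when not locatable — and `message`).
#' @export
validate_msa <- function(source, format = c("fasta", "a2m", "a3m", "sto",
                                            "aln", "clustal", "pfam"),
                         alphabet = "protein") {
  format <- match.arg(format)
  alphabet <- as_alphabet(alphabet)
  lines <- source_lines(source)
  issues <- list()
  nbidx <- which(nzchar(trimws(lines)))
  if (!length(nbidx)) {
    issues[[1L]] <- new_issue("error", NULL, "empty alignment")
    return(validation_report(issues))
  }

  if (format %in% c("fasta", "a2m", "a3m")) {
    if (!startsWith(trimws(lines[nbidx[1]]), ">"))
      issues[[length(issues) + 1L]] <- new_issue(
        "error", nbidx[1], "expected a '>' header as the first record line")
    rec_len <- integer(); rec_match <- integer(); rec_line <- integer()
    cur <- 0L
    for (k in nbidx) {
      t <- trimws(lines[k])
      if (startsWith(t, ">")) {
        cur <- cur + 1L
        rec_len[cur] <- 0L; rec_match[cur] <- 0L; rec_line[cur] <- k
        if (!nzchar(sub("^>", "", sub("[ \t].*$", "", t))))
          issues[[length(issues) + 1L]] <- new_issue("error", k, "empty record id")
      } else if (cur > 0L) {
        issues <- check_seq_chars(t, k, alphabet, issues)
        rec_len[cur] <- rec_len[cur] + nchar(t)
        cc <- strsplit(t, "", fixed = TRUE)[[1]]
        rec_match[cur] <- rec_match[cur] + sum(cc %in% c(LETTERS, "-") & cc != ".")
        rec_line[cur] <- k
      }
    }
    if (cur == 0L)
      issues[[length(issues) + 1L]] <- new_issue("error", NULL, "no records found")
    else if (any(rec_len == 0L))
      issues[[length(issues) + 1L]] <- new_issue(
        "error", rec_line[which(rec_len == 0L)[1]], "record has no sequence")
    else if (format == "fasta")
      issues <- check_equal_lengths(rec_len, rec_line, "sequence", issues)
    else
      issues <- check_equal_lengths(rec_match, rec_line, "match-column", issues)
  } else if (format == "sto") {
    if (!startsWith(trimws(lines[nbidx[1]]), "# STOCKHOLM"))
      issues[[length(issues) + 1L]] <- new_issue(
        "error", nbidx[1], "missing '# STOCKHOLM' header line")
    if (!any(trimws(lines) == "//"))
      issues[[length(issues) + 1L]] <- new_issue(
        "error", NULL, "missing '//' terminator")
    issues <- validate_id_seq_lines(lines, nbidx, alphabet, issues,
                                    allow_blocks = TRUE)
  } else if (format == "clustal") {
    if (!grepl("^CLUSTAL", trimws(lines[nbidx[1]]), ignore.case = TRUE))
      issues[[length(issues) + 1L]] <- new_issue(
        "error", nbidx[1], "missing CLUSTAL header line")
    ids <- character(); lens <- integer(); lastline <- integer()
    for (k in nbidx[-1]) {
      line <- lines[k]
      if (grepl("^[ \t]", line)) next
      f <- strsplit(trimws(line), "[ \t]+")[[1]]
      if (length(f) < 2L) {
        issues[[length(issues) + 1L]] <- new_issue(
          "error", k, "expected 'id chunk' line")
        next
      }
      issues <- check_seq_chars(f[2], k, alphabet, issues)
      i <- match(f[1], ids)
      if (is.na(i)) { ids <- c(ids, f[1]); lens <- c(lens, nchar(f[2]))
                      lastline <- c(lastline, k) }
      else { lens[i] <- lens[i] + nchar(f[2]); lastline[i] <- k }
    }
    if (!length(ids))
      issues[[length(issues) + 1L]] <- new_issue("error", NULL, "no records found")
    issues <- check_equal_lengths(lens, lastline, "sequence", issues)
  } else if (format == "pfam") {
    issues <- validate_id_seq_lines(lines, nbidx, alphabet, issues,
                                    allow_blocks = FALSE)
  } else if (format == "aln") {
    lens <- integer(); at <- integer()
    for (k in nbidx) {
      t <- trimws(lines[k])
      if (!grepl("^[A-Za-z.-]+$", t)) {
        issues <- check_seq_chars(t, k, alphabet, issues)
        if (grepl("[ \t]", t))
          issues[[length(issues) + 1L]] <- new_issue(
            "error", k, "ALN rows must be bare aligned sequences")
        next
      }
      issues <- check_seq_chars(t, k, alphabet, issues)
      lens <- c(lens, nchar(t)); at <- c(at, k)
    }
    if (!length(lens))
      issues[[length(issues) + 1L]] <- new_issue("error", NULL, "no records found")
    issues <- check_equal_lengths(lens, at, "sequence", issues)
  }
  validation_report(issues)
}

validate_id_seq_lines <- function(lines, nbidx, alphabet, issues, allow_blocks) {
  ids <- character(); lens <- integer(); lastline <- integer()
  for (k in nbidx) {
    t <- trimws(lines[k])
    if (startsWith(t, "#") || t == "//") next
    f <- strsplit(t, "[ \t]+")[[1]]
    if (length(f) != 2L) {
      issues[[length(issues) + 1L]] <- new_issue(
        "error", k, "expected one 'id sequence' pair per line")
      next
    }
    issues <- check_seq_chars(f[2], k, alphabet, issues)
    i <- match(f[1], ids)
    if (is.na(i)) { ids <- c(ids, f[1]); lens <- c(lens, nchar(f[2]))
                    lastline <- c(lastline, k) }
    else if (allow_blocks) { lens[i] <- lens[i] + nchar(f[2]); lastline[i] <- k }
    else issues[[length(issues) + 1L]] <- new_issue(
      "error", k, sprintf("duplicate id '%s'", f[1]))
  }
  if (!length(ids))
    issues[[length(issues) + 1L]] <- new_issue("error", NULL, "no records found")
  check_equal_lengths(lens, lastline, "sequence", issues)
}

validation_report <- function(issues) {
  df <- if (length(issues)) do.call(rbind, issues)
        else data.frame(severity = character(), line = integer(),
                        message = character(), stringsAsFactors = FALSE)
  structure(list(ok = !any(df$severity == "error"), issues = df),
            class = "msa_validation")
}

#' @export
print.msa_validation <- function(x, ...) {
  if (x$ok && nrow(x$issues) == 0L) {
    cat("OK: alignment is valid\n")
  } else {
    cat(if (x$ok) "OK (with warnings):\n" else "INVALID:\n")
    for (i in seq_len(nrow(x$issues))) {
      loc <- if (is.na(x$issues$line[i])) "" else paste0(" (line ", x$issues$line[i], ")")
      cat(sprintf("  [%s]%s %s\n", x$issues$severity[i], loc, x$issues$message[i]))
    }
  }
  invisible(x)
}
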