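#' Biological sequence alphabets
#'
#' Defines the character sets used to encode and validate alignments. Each
#' alphabet has a standard symbol set (the 20 amino acids, or the 4
#' nucleotides), a non-standard set (ambiguity/rare codes: `B J O U X Z` for
#' protein, the IUPAC ambiguity letters plus `X` for DNA/RNA), and the two
#' gap characters `-` and `.`. The three sets are pairwise disjoint; any
#' other character is rejected during encoding and flagged by validation.
#'
#' @param name One of `"protein"`, `"dna"`, `"rna"`.
#' @return An object of class `msa_alphabet` with elements `name`,
#'   `standard`, `non_standard` and `gaps`.
#' @examples
#' msa_alphabet("protein")$standard
#' msa_alphabet("rna")$non_standard
#' @export
msa_alphabet <- function(name = c("protein", "dna", "rna")) {
  name <- match.arg(name)
  standard <- switch(name,
    protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
    dna     = c("A", "C", "G", "T"),
    rna     = c("A", "C", "G", "U"))
  non_standard <- switch(name,
    protein = c("B", "J", "O", "U", "X", "Z"),
    dna     = c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "X"),
    rna     = c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "X"))
  structure(list(name = name, standard = standard,
                 non_standard = non_standard, gaps = c("-", ".")),
            class = "msa_alphabet")
}

as_alphabet <- function(x) {
  if (inherits(x, "msa_alphabet")) return(x)
  if (is.character(x) && length(x) == 1L) return(msa_alphabet(x))
  stop_neffr("'alphabet' must be an msa_alphabet or one of 'protein','dna','rna'",
             "option")
}

#' @export
print.msa_alphabet <- function(x, ...) {
  cat("<msa_alphabet>", x$name, "\n")
  cat("  standard:     ", paste(x$standard, collapse = ""), "\n")
  cat("  non-standard: ", paste(x$non_standard, collapse = ""), "\n")
  cat("  gaps:         ", paste(x$gaps, collapse = " "), "\n")
  invisible(x)
}

# integer code lookup indexed by (ASCII code + 1); NA marks a rejected char.
# Gap code is 0. Standard symbols get 1..k; non-standard symbols get k+1..
# under as_standard, or 0 (gap) under as_gap. Lowercase maps like uppercase.
alphabet_lookup <- function(alphabet, policy) {
  k <- length(alphabet$standard)
  syms <- c(alphabet$standard, alphabet$non_standard, alphabet$gaps)
  codes <- c(seq_len(k),
             if (policy == "as_standard") k + seq_along(alphabet$non_standard)
             else rep(0L, length(alphabet$non_standard)),
             0L, 0L)
  lookup <- rep(NA_integer_, 128L)
  idx <- vapply(syms, utf8ToInt, integer(1))
  lookup[idx + 1L] <- codes
  lower <- vapply(tolower(c(alphabet$standard, alphabet$non_standard)),
                  utf8ToInt, integer(1))
  lookup[lower + 1L] <- codes[seq_along(lower)]
  attr(lookup, "symbol_map") <-
    stats::setNames(as.integer(codes), syms)
  lookup
}

#' Encode an alignment as an integer matrix
#'
#' Maps every character of a column-aligned MSA to an integer code over the
#' given alphabet. Case is folded first (A2M/A3M case semantics must be
#' resolved by [resolve_insertions()] before encoding); both `-` and `.`
#' map to the reserved gap code 0. Under the `as_gap` policy all
#' non-standard symbols also map to the gap code; under `as_standard`
#' (the default) each keeps its own distinct code.
#'
#' @param msa An [msa] object whose records all have equal length.
#' @param alphabet An [msa_alphabet] or its name.
#' @param non_standard `"as_standard"` or `"as_gap"`.
#' @return An object of class `encoded_msa`: list with `matrix` (N x L
#'   integer), `gap_code` (0), `symbol_map` (named integer vector),
#'   `column_map` (1-based original column index per current column),
#'   `ids`, `alphabet`, `policy`.
#' @seealso [decode_msa()], [compute_neff()]
#' @export
encode_msa <- function(msa, alphabet = msa_alphabet("protein"),
                       non_standard = c("as_standard", "as_gap")) {
  policy <- match.arg(non_standard)
  alphabet <- as_alphabet(alphabet)
  msa <- as_msa(msa)
  lens <- nchar(msa$seqs)
  if (length(unique(lens)) != 1L)
    stop_neffr("records have unequal aligned lengths; resolve insertions first",
               "encoding")
  L <- lens[1]
  if (L < 1L) stop_neffr("empty alignment", "encoding")
  lookup <- alphabet_lookup(alphabet, policy)
  n <- length(msa$seqs)
  mat <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    ints <- utf8ToInt(msa$seqs[i])
    bad <- ints >= 128L
    v <- ifelse(bad, NA_integer_, lookup[pmin(ints, 127L) + 1L])
    if (anyNA(v)) {
      col <- which(is.na(v))[1]
      stop_neffr(sprintf(
        "invalid character '%s' for alphabet '%s' in record '%s' at column %d",
        substr(msa$seqs[i], col, col), alphabet$name, msa$ids[i], col),
        "encoding")
    }
    mat[i, ] <- v
  }
  structure(list(matrix = mat, gap_code = 0L,
                 symbol_map = attr(lookup, "symbol_map"),
                 column_map = seq_len(L), ids = msa$ids,
                 alphabet = alphabet$name, policy = policy),
            class = "encoded_msa")
}

#' Decode an encoded alignment back to character rows
#'
#' Inverts [encode_msa()]: each code maps back to its (uppercase) symbol and
#' the gap code to `-`. Symbols remapped to the gap code by the `as_gap`
#' policy decode to `-` (that information is not recoverable).
#'
#' @param encoded An `encoded_msa`.
#' @return Character vector of rows, named by record id.
#' @export
decode_msa <- function(encoded) {
  stopifnot(inherits(encoded, "encoded_msa"))
  sm <- encoded$symbol_map
  codes <- sort(unique(unname(sm[sm > 0L])))
  inv <- character(max(c(0L, codes)) + 1L)
  inv[1L] <- "-"
  for (cd in codes) inv[cd + 1L] <- names(sm)[match(cd, sm)]
  rows <- apply(encoded$matrix, 1L, function(r) paste(inv[r + 1L], collapse = ""))
  stats::setNames(rows, encoded$ids)
}
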