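#' The 21-letter amino-acid alphabet
#'
#' The alphabet used for one-hot encoding: the 20 standard residues in the
#' fixed order `ACDEFGHIKLMNPQRSTVWY`, followed by `X`, which doubles as the
#' padding character and the stand-in for unknown residues. Alanine sits at
#' index 0 (first position).
#'
#' @return An object of class `neoimm_alphabet`: a list with `symbols`
#'   (character vector of length 21) and `pad_symbol` (`"X"`).
#' @examples
#' ab <- aa_alphabet()
#' length(ab$symbols)  # 21
#' @export
aa_alphabet <- function() {
  symbols <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  structure(
    list(symbols = symbols, pad_symbol = "X"),
    class = "neoimm_alphabet"
  )
}

#' @export
print.neoimm_alphabet <- function(x, ...) {
  cat("Amino-acid alphabet (", length(x$symbols), " symbols): ",
      paste(x$symbols, collapse = ""), "\n",
      "pad/unknown symbol: ", x$pad_symbol, "\n", sep = "")
  invisible(x)
}

#' One-hot encode a single residue
#'
#' Returns a binary vector of length 21 with a single 1 at the alphabet index
#' of `residue`. Residues outside the alphabet (e.g. `B`, `Z`, `U`) are mapped
#' to the pad/unknown symbol `X` with a warning.
#'
#' @param residue A single uppercase character.
#' @param alphabet An alphabet from [aa_alphabet()].
#' @return Integer vector of length 21 summing to 1.
#' @examples
#' encode_residue("A")  # 1 at position 1
#' @export
encode_residue <- function(residue, alphabet = aa_alphabet()) {
  if (!is.character(residue) || length(residue) != 1L || nchar(residue) != 1L) {
    stop("invalid residue: expected a single character, got ",
         deparse(substitute(residue)), call. = FALSE)
  }
  idx <- match(residue, alphabet$symbols)
  if (is.na(idx)) {
    warning("unknown residue '", residue, "' mapped to '",
            alphabet$pad_symbol, "'", call. = FALSE)
    idx <- match(alphabet$pad_symbol, alphabet$symbols)
  }
  v <- integer(length(alphabet$symbols))
  v[idx] <- 1L
  v
}

# Vectorized residue -> alphabet index (1-based); unknowns -> pad index.
# Used by the encoders; warns once per call if unknowns were remapped.
residue_indices <- function(residues, alphabet) {
  idx <- match(residues, alphabet$symbols)
  bad <- is.na(idx)
  if (any(bad)) {
    warning("unknown residue(s) ",
            paste(unique(residues[bad]), collapse = ", "),
            " mapped to '", alphabet$pad_symbol, "'", call. = FALSE)
    idx[bad] <- match(alphabet$pad_symbol, alphabet$symbols)
  }
  idx
}

#' One-hot encode a peptide into a fixed-shape 11 x 21 matrix
#'
#' Peptides of length 8 to 11 are encoded row-by-row; shorter peptides are
#' right-padded (C-terminal) with the pad symbol so that the matrix shape is
#' constant regardless of peptide length -- the network's input contract.
#'
#' @param peptide A peptide string, 8--11 residues after whitespace stripping.
#' @param alphabet An alphabet from [aa_alphabet()].
#' @param max_len Padded length (default 11).
#' @param pad Padding placement, `"right"` (default, C-terminal) or `"center"`.
#' @return Binary matrix with `max_len` rows and 21 columns; each row sums
#'   to 1.
#' @examples
#' m <- encode_peptide("SIINFEKL")
#' dim(m)  # 11 21
#' @export
encode_peptide <- function(peptide, alphabet = aa_alphabet(), max_len = 11L,
                           pad = c("right", "center")) {
  pad <- match.arg(pad)
  peptide <- gsub("\\s", "", peptide)
  L <- nchar(peptide)
  if (L < 8L || L > max_len) {
    stop("peptide '", peptide, "' has length ", L,
         "; expected 8-", max_len, call. = FALSE)
  }
  residues <- strsplit(toupper(peptide), "")[[1]]
  n_pad <- max_len - L
  pad_sym <- alphabet$pad_symbol
  if (pad == "right") {
    residues <- c(residues, rep(pad_sym, n_pad))
  } else {
    left <- n_pad %/% 2L
    residues <- c(rep(pad_sym, left), residues, rep(pad_sym, n_pad - left))
  }
  idx <- residue_indices(residues, alphabet)
  m <- matrix(0L, nrow = max_len, ncol = length(alphabet$symbols))
  m[cbind(seq_len(max_len), idx)] <- 1L
  rownames(m) <- residues
  colnames(m) <- alphabet$symbols
  m
}

#' Normalize an HLA allele name to 4-digit resolution
#'
#' Accepts common dialects and returns the canonical
#' `HLA-<locus>*<group>:<protein>` form, truncating higher-resolution fields
#' (synonymous / non-coding suffixes). Examples of accepted input:
#' `"HLA-A*02:01:01"`, `"HLA-A02:01"`, `"A*02:01"`, `"A0201"`,
#' `"HLA-B*5701"`. Strings that do not resolve to 4-digit (protein-level)
#' resolution, such as `"HLA-A2"`, raise an error.
#'
#' @param raw Character vector of allele names.
#' @return Character vector of normalized names, same length.
#' @examples
#' normalize_allele_name("A0201")  # "HLA-A*02:01"
#' @export
normalize_allele_name <- function(raw) {
  if (length(raw) == 0L) stop("empty allele name", call. = FALSE)
  vapply(raw, normalize_one_allele, character(1), USE.NAMES = FALSE)
}

normalize_one_allele <- function(raw) {
  if (is.na(raw) || !nzchar(trimws(raw))) {
    stop("cannot parse allele name: empty or NA", call. = FALSE)
  }
  s <- toupper(gsub("\\s", "", raw))
  s <- sub("^HLA-?", "", s)
  # locus = letters possibly followed by digits (A, B, C, E, DRB1, ...)
  m <- regmatches(s, regexec("^([A-Z]+[0-9]*?)\\*?([0-9]{2,3}):([0-9]{2,3})", s))[[1]]
  if (length(m) == 4L && grepl(":", s)) {
    return(sprintf("HLA-%s*%s:%s", m[2], m[3], m[4]))
  }
  # compact form without colon: A0201, B*5701 (2+2 digits only)
  m <- regmatches(s, regexec("^([A-Z]+)\\*?([0-9]{2})([0-9]{2})$", s))[[1]]
  if (length(m) == 4L) {
    return(sprintf("HLA-%s*%s:%s", m[2], m[3], m[4]))
  }
  stop("cannot parse allele name '", raw,
       "' to 4-digit resolution", call. = FALSE)
}

# TRUE where the allele string resolves to 4-digit form, without erroring.
allele_resolvable <- function(raw) {
  vapply(raw, function(a) {
    !inherits(try(normalize_one_allele(a), silent = TRUE), "try-error")
  }, logical(1), USE.NAMES = FALSE)
}

#' MHC contact positions used by the pseudo-sequence representation
#'
#' The class I residue positions in contact with the bound peptide whose
#' concatenation forms the allele pseudo-sequence.
#'
#' @return Integer vector of 33 positions.
#' @export
pseudo_positions <- function() {
  c(79L, 24L, 45L, 59L, 62L, 63L, 66L, 67L, 69L, 70L, 73L, 74L, 76L, 77L,
    80L, 81L, 84L, 95L, 97L, 99L, 114L, 116L, 118L, 143L, 147L, 150L,
    152L, 156L, 158L, 159L, 163L, 167L, 171L)
}

#' Read an allele pseudo-sequence table
#'
#' Two-column whitespace-delimited text: allele name, then the pseudo-sequence
#' residue string. Lines starting with `#` are ignored. All sequences must
#' share one length; allele names are normalized to 4-digit form.
#'
#' @param path Path to the table file.
#' @param alphabet Alphabet used to validate residues.
#' @return A `neoimm_pseudo_table`: named character vector of pseudo-sequences
#'   keyed by normalized allele, with attributes `pseudo_length` and
#'   `positions`.
#' @export
read_pseudo_table <- function(path, alphabet = aa_alphabet()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("pseudo-sequence table is empty", call. = FALSE)
  parts <- strsplit(lines, "[ \t]+")
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    stop("malformed pseudo-sequence line: '", lines[which(bad)[1]], "'",
         call. = FALSE)
  }
  alleles <- vapply(parts, `[`, character(1), 1L)
  seqs <- toupper(vapply(parts, `[`, character(1), 2L))
  pseudo_table(stats::setNames(seqs, alleles), alphabet = alphabet)
}

#' Construct a pseudo-sequence table from a named vector
#'
#' @param entries Named character vector: allele name -> residue string.
#' @param positions Source residue positions (metadata only); defaults to
#'   [pseudo_positions()] when the sequence length matches, `NULL` otherwise.
#' @param alphabet Alphabet used to validate residues.
#' @return A `neoimm_pseudo_table` object.
#' @export
pseudo_table <- function(entries, positions = NULL, alphabet = aa_alphabet()) {
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("pseudo-sequence entries must be named by allele", call. = FALSE)
  }
  lens <- nchar(entries)
  if (length(unique(lens)) != 1L) {
    stop("pseudo-sequences have inconsistent lengths: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  plen <- lens[[1]]
  residues <- unique(strsplit(paste(entries, collapse = ""), "")[[1]])
  alien <- setdiff(residues, alphabet$symbols)
  if (length(alien) > 0L) {
    stop("pseudo-sequence contains non-alphabet residues: ",
         paste(alien, collapse = ", "), call. = FALSE)
  }
  names(entries) <- normalize_allele_name(names(entries))
  if (anyDuplicated(names(entries))) {
    entries <- entries[!duplicated(names(entries))]
  }
  if (is.null(positions) && plen == length(pseudo_positions())) {
    positions <- pseudo_positions()
  }
  structure(entries, pseudo_length = plen, positions = positions,
            class = "neoimm_pseudo_table")
}

#' @export
print.neoimm_pseudo_table <- function(x, ...) {
  cat("MHC pseudo-sequence table: ", length(x), " alleles, length ",
      attr(x, "pseudo_length"), "\n", sep = "")
  utils::head(cbind(allele = names(x), pseudo = unclass(x)), 5)
  invisible(x)
}

#' One-hot encode an MHC allele via its pseudo-sequence
#'
#' @param allele_name Allele name in any dialect [normalize_allele_name()]
#'   accepts.
#' @param table A pseudo-sequence table from [read_pseudo_table()] or
#'   [pseudo_table()].
#' @param alphabet An alphabet from [aa_alphabet()].
#' @return Binary matrix, pseudo-length rows x 21 columns, row i encoding
#'   residue i of the pseudo-sequence.
#' @export
encode_allele <- function(allele_name, table, alphabet = aa_alphabet()) {
  key <- normalize_allele_name(allele_name)
  seqs <- unclass(table)[key]
  if (any(is.na(seqs))) {
    stop("allele(s) not in pseudo-sequence table: ",
         paste(key[is.na(seqs)], collapse = ", "), call. = FALSE)
  }
  if (length(key) == 1L) {
    residues <- strsplit(seqs[[1]], "")[[1]]
    idx <- residue_indices(residues, alphabet)
    m <- matrix(0L, nrow = length(idx), ncol = length(alphabet$symbols))
    m[cbind(seq_along(idx), idx)] <- 1L
    rownames(m) <- residues
    colnames(m) <- alphabet$symbols
    return(m)
  }
  lapply(seqs, function(s) encode_allele_seq(s, alphabet))
}

encode_allele_seq <- function(seq, alphabet) {
  residues <- strsplit(seq, "")[[1]]
  idx <- residue_indices(residues, alphabet)
  m <- matrix(0L, nrow = length(idx), ncol = length(alphabet$symbols))
  m[cbind(seq_along(idx), idx)] <- 1L
  m
}

#' Decode a one-hot peptide matrix back to a string
#'
#' Argmax-decodes each row and strips trailing pad symbols; the inverse of
#' [encode_peptide()] for peptides without unknown residues.
#'
#' @param m Binary matrix from [encode_peptide()].
#' @param alphabet The alphabet used for encoding.
#' @return Peptide string.
#' @export
decode_peptide <- function(m, alphabet = aa_alphabet()) {
  sym <- alphabet$symbols[apply(m, 1L, which.max)]
  s <- paste(sym, collapse = "")
  sub(paste0(alphabet$pad_symbol, "+$"), "", s)
}

# Stable content checksum of alphabet + pseudo table, to detect
# encoder/model mismatches at prediction time. Polynomial rolling hash.
encoding_hash <- function(alphabet, table) {
  txt <- paste(c(paste(alphabet$symbols, collapse = ""),
                 names(table), unclass(table)), collapse = "|")
  h <- 0
  for (k in utf8ToInt(txt)) h <- (h * 131 + k) %% 2147483647
  sprintf("%d:%d", nchar(txt), h)
}
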