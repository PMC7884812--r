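#' @useDynLib fourmer, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' The 21-letter protein alphabet
#'
#' The 20 standard amino acids plus `X` (unknown residue), in alphabetical
#' order. Integer residue codes are assigned by position in this vector
#' (0-based), so packed 4-mer codes are reproducible across runs and
#' platforms.
#'
#' @format A character vector of length 21.
#' @export
PROTEIN_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "X", "Y")

#' Normalize residue letters to the 21-letter alphabet
#'
#' Upper-cases the input and maps every letter outside the 20 standard amino
#' acids to `X`: the ambiguity codes `B`, `Z`, `J`, the rare residues `U`
#' (selenocysteine) and `O` (pyrrolysine), the stop symbol `*`, and any other
#' character. Keeping the alphabet at exactly 21 letters is what the
#' frequency-based alphabet clustering assumes.
#'
#' @param letters A character scalar of residue letters.
#' @return A character scalar over `PROTEIN_ALPHABET`.
#' @export
normalize_letters <- function(letters) {
  stopifnot(is.character(letters), length(letters) == 1L)
  x <- strsplit(toupper(letters), "", fixed = TRUE)[[1]]
  x[!(x %in% PROTEIN_ALPHABET)] <- "X"
  paste0(x, collapse = "")
}

#' Read a protein FASTA file
#'
#' Parses `>`-header records: the record id is the first whitespace-delimited
#' token of the header, the rest is the description. Wrapped sequence lines
#' are concatenated, whitespace is stripped and letters are upper-cased.
#' Blank lines are ignored. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with character columns `id`, `description`,
#'   `letters`, one row per record.
#' @export
read_fasta <- function(path) {
  raw <- readLines(path, warn = FALSE)
  lines <- trimws(raw)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no sequences in '", path, "'")
  if (!startsWith(lines[[1]], ">"))
    stop("FASTA parse error in '", path, "': sequence line before any header")
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in '", path, "'")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  letters <- toupper(as.character(set))
  if (any(!nzchar(letters)))
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(letters)], collapse = ", "))
  data.frame(id = ids, description = desc, letters = unname(letters),
             stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: headers are `>id description` (or `>id` when
#' the description is empty), sequences wrapped at `width` columns.
#'
#' @param records A data.frame with columns `id`, `letters` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "letters") %in% names(records)))
  set <- Biostrings::AAStringSet(records$letters)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Parse a substitution matrix in NCBI plain-text format
#'
#' The format used by the standard BLOSUM/PAM distribution files:
#' `#`-prefixed comment lines, one header row of letters, then one row per
#' letter starting with its label. Header and row letter orders may differ;
#' cells are resolved by letter, not position. The matrix must be symmetric.
#'
#' @param path Path to a matrix file, e.g. `blosum62_path()`.
#' @return An integer matrix with identical row and column letter dimnames.
#' @export
parse_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no header in matrix file '", path, "'")
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (any(nchar(header) != 1L))
    stop("no header in matrix file '", path, "': expected single-letter columns")
  n <- length(header)
  m <- matrix(NA_integer_, n, n, dimnames = list(header, header))
  for (ln in lines[-1]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    rowletter <- tok[[1]]
    if (!(rowletter %in% header))
      stop("matrix row letter '", rowletter, "' not in header")
    vals <- suppressWarnings(as.integer(tok[-1]))
    if (length(vals) != n || anyNA(vals))
      stop("malformed matrix row for letter '", rowletter, "'")
    m[rowletter, ] <- vals
  }
  missing <- header[apply(m, 1L, anyNA)]
  if (length(missing) > 0L)
    stop("missing matrix row(s) for header letter(s): ",
         paste(missing, collapse = ", "))
  bad <- which(m != t(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("asymmetric matrix entry for pair ",
         rownames(m)[bad[1L, 1L]], "/", colnames(m)[bad[1L, 2L]])
  storage.mode(m) <- "integer"
  m
}

#' Path to a bundled scoring matrix
#'
#' BLOSUM45, BLOSUM62 and BLOSUM80 are shipped with the package in NCBI
#' plain-text format; BLOSUM62 is the search default.
#'
#' @param name Matrix name, one of `"BLOSUM45"`, `"BLOSUM62"`, `"BLOSUM80"`.
#' @return Path to the bundled file.
#' @export
blosum_path <- function(name = "BLOSUM62") {
  name <- match.arg(name, c("BLOSUM45", "BLOSUM62", "BLOSUM80"))
  system.file("extdata", name, package = "fourmer", mustWork = TRUE)
}

#' @rdname blosum_path
#' @export
blosum62_path <- function() blosum_path("BLOSUM62")

#' Encode a protein record under a cluster map
#'
#' Letters are first normalized with [normalize_letters()], then each letter
#' is replaced by the integer code of its cluster representative under
#' `cmap`. Codes are the 0-based positions of the representative letters in
#' `PROTEIN_ALPHABET` (alphabetical, fixed), so packed 4-mer integers are
#' reproducible. Encoding is length-preserving and idempotent.
#'
#' @param record A list or one-row data.frame with fields `id` and `letters`.
#' @param cmap A cluster map from [build_cluster_map()].
#' @return An object of class `encoded_seq`: a list with `id`, `codes`
#'   (integer vector, one code per residue), `length`, `k` and `cmap_sig`
#'   (a signature used to reject mixed-alphabet comparisons).
#' @export
encode_sequence <- function(record, cmap) {
  stopifnot(inherits(cmap, "cluster_map"))
  letters <- record$letters
  if (is.null(letters) || !nzchar(letters))
    stop("cannot encode empty sequence", if (!is.null(record$id))
      paste0(" '", record$id, "'") else "")
  x <- strsplit(normalize_letters(letters), "", fixed = TRUE)[[1]]
  codes <- unname(cmap$codes[x])
  structure(
    list(id = record$id, codes = as.integer(codes), length = length(codes),
         k = cmap$k, cmap_sig = cmap$signature),
    class = "encoded_seq"
  )
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat(sprintf("<encoded_seq '%s': %d residues, alphabet k=%d>\n",
              x$id, x$length, x$k))
  invisible(x)
}
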