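#' Pack four residue codes into one 32-bit 4-mer code
#'
#' Byte `i` of the packed integer is the code at position `i` (little-endian
#' position order): `code1 + 256*code2 + 256^2*code3 + 256^3*code4`. The
#' packing is bijective over 4-tuples of codes in \[0, 255\]. Codes are
#' returned as doubles because R has no native unsigned 32-bit integer; all
#' values are exactly representable.
#'
#' @param codes4 An integer vector of exactly four residue codes in
#'   \[0, 255\].
#' @return A numeric scalar, the packed 4-mer code.
#' @export
pack_4mer <- function(codes4) {
  if (length(codes4) != 4L) stop("pack_4mer expects exactly 4 residue codes")
  if (any(codes4 < 0) || any(codes4 > 255))
    stop("residue codes must be in [0, 255]")
  sum(as.numeric(codes4) * c(1, 256, 65536, 16777216))
}

# Vectorized packing of all 4-mers of a code vector at the given 0-based
# offsets; offsets must satisfy offset + 4 <= length(codes).
pack_4mers_at <- function(codes, offsets) {
  codes <- as.numeric(codes)
  i <- offsets + 1L
  codes[i] + 256 * codes[i + 1L] + 65536 * codes[i + 2L] +
    16777216 * codes[i + 3L]
}

#' Index a subject's 4-mers as packed 32-bit codes
#'
#' Full mode (`fast = FALSE`) packs the 4-mer at every offset `0 .. N-4`
#' (stride 1), mirroring an in-memory quadruplication of the subject; fast
#' mode (`fast = TRUE`) packs even offsets only (stride 2, starting at 0),
#' the non-exhaustive variant that halves filter work at the cost of
#' sensitivity. Subjects shorter than 4 residues yield an empty code set.
#'
#' @param subject An `encoded_seq` from [encode_sequence()].
#' @param fast Logical; index even offsets only.
#' @return An object of class `kmer_codes`: a list with `subject_id`, `step`
#'   (1 or 2), `codes` (numeric vector of packed 4-mers, in offset order),
#'   `n_residues`, `k` and `cmap_sig`.
#' @export
build_kmer_codes <- function(subject, fast = FALSE) {
  stopifnot(inherits(subject, "encoded_seq"), is.logical(fast))
  step <- if (fast) 2L else 1L
  n <- subject$length
  offsets <- if (n >= 4L) seq.int(0L, n - 4L, by = step) else integer(0)
  codes <- if (length(offsets) > 0L) pack_4mers_at(subject$codes, offsets)
           else numeric(0)
  structure(
    list(subject_id = subject$id, step = step, codes = codes,
         n_residues = n, k = subject$k, cmap_sig = subject$cmap_sig),
    class = "kmer_codes"
  )
}

#' Query 4-mer match vector against an indexed subject
#'
#' Bit `i` is `TRUE` iff the query 4-mer starting at position `i` occurs
#' anywhere among the subject's indexed 4-mers; the subject-side position is
#' not recorded. Query and subject must be encoded under the same cluster
#' map. Queries shorter than 4 residues give a zero-length vector.
#'
#' @param query An `encoded_seq`.
#' @param subject_codes A `kmer_codes` object for the subject.
#' @return A logical vector of length `max(M - 3, 0)`.
#' @export
match_vector <- function(query, subject_codes) {
  stopifnot(inherits(query, "encoded_seq"), inherits(subject_codes, "kmer_codes"))
  if (!identical(query$cmap_sig, subject_codes$cmap_sig))
    stop("query and subject are encoded under different cluster maps")
  m <- query$length
  if (m < 4L || length(subject_codes$codes) == 0L)
    return(logical(max(m - 3L, 0L)))
  qcodes <- pack_4mers_at(query$codes, seq.int(0L, m - 4L))
  qcodes %in% subject_codes$codes
}

#' Sliding-window ("nearby") filter decision over a match vector
#'
#' Emulates a 16-bit shift register scanned left to right over the query
#' 4-mer match bits: after each shift-and-set, the decision passes as soon
#' as the number of set bits strictly exceeds `n`. Equivalently, the filter
#' passes iff some window of at most 16 consecutive query 4-mer positions
#' contains at least `n + 1` matches. With the default `n = 3` this demands
#' four 4-mer matches within a query window of 16 consecutive residues.
#'
#' @param mv Logical match vector from [match_vector()].
#' @param n Nearby threshold, an integer in \[1, 15\]; the window popcount
#'   must strictly exceed it.
#' @return A list with `passed` (logical) and `first_pass_index` (1-based
#'   query 4-mer index at which the threshold was first exceeded, or `NA`).
#' @export
nearby_pass <- function(mv, n = 3L) {
  if (!is.numeric(n) || length(n) != 1L || n != as.integer(n) ||
      n < 1L || n > 15L)
    stop("nearby threshold n must be an integer in [1, 15]")
  mv <- as.logical(mv)
  if (length(mv) == 0L)
    return(list(passed = FALSE, first_pass_index = NA_integer_))
  cs <- cumsum(mv)
  lag <- c(rep(0, min(16L, length(mv))),
           cs[seq_len(max(length(mv) - 16L, 0L))])
  win <- cs - lag  # popcount of the register after position i
  idx <- which(win > n)
  if (length(idx) == 0L)
    list(passed = FALSE, first_pass_index = NA_integer_)
  else
    list(passed = TRUE, first_pass_index = idx[[1]])
}

#' Decide whether a subject is promising enough to align
#'
#' Composition of [match_vector()] and [nearby_pass()]: the subject passes
#' when some 16-position query window holds more than `n` exact 4-mer
#' matches. Degenerate inputs (query shorter than 4 residues, or an empty
#' subject index) fail the filter silently, since they cannot hold a 4-mer.
#'
#' @inheritParams match_vector
#' @inheritParams nearby_pass
#' @return As [nearby_pass()].
#' @export
filter_subject <- function(query, subject_codes, n = 3L) {
  nearby_pass(match_vector(query, subject_codes), n)
}
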