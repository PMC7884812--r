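#' Affine gap penalty model
#'
#' A gap of length `L >= 1` costs `gap_open + (L - 1) * gap_extend`: the
#' first gap residue costs `gap_open` alone, each further residue
#' `gap_extend`. Note that some tools instead charge `gap_open + gap_extend`
#' for the first residue; with this convention the defaults 11/1 match the
#' standard blastp BLOSUM62 pairing.
#'
#' @param gap_open Positive integer cost of the first residue of a gap.
#' @param gap_extend Positive integer cost of each subsequent gap residue.
#' @return An object of class `gap_model`.
#' @export
gap_model <- function(gap_open = 11L, gap_extend = 1L) {
  if (!is.numeric(gap_open) || length(gap_open) != 1L || gap_open < 1 ||
      gap_open != as.integer(gap_open))
    stop("gap_open must be a positive integer")
  if (!is.numeric(gap_extend) || length(gap_extend) != 1L || gap_extend < 1 ||
      gap_extend != as.integer(gap_extend))
    stop("gap_extend must be a positive integer")
  structure(list(gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "gap_model")
}

#' Exact Smith-Waterman local alignment score with affine gaps
#'
#' Computes the maximal local alignment score between two residue strings
#' under the Gotoh recurrences
#' \deqn{H_{ij} = \max(0,\ H_{i-1,j-1} + s(a_i, b_j),\ E_{ij},\ F_{ij})}
#' \deqn{E_{ij} = \max(H_{i,j-1} - o,\ E_{i,j-1} - e)}
#' \deqn{F_{ij} = \max(H_{i-1,j} - o,\ F_{i-1,j} - e)}
#' with gap open cost `o` and extension cost `e`. The score is the maximum
#' of `H` over all cells; ties resolve to the smallest `(query_end,
#' subject_end)` in row-major order. Only the score and the end coordinates
#' of the best cell are reported; no traceback is produced.
#'
#' Letters are normalized as in [encode_sequence()] but *never*
#' cluster-collapsed: alignment always scores original residues against the
#' unmodified matrix, whatever reduced alphabet the filter stage used.
#'
#' @param a,b Character scalars of residue letters (query and subject).
#' @param m Scoring matrix from [parse_score_matrix()]; must cover all
#'   normalized letters (the bundled BLOSUM matrices include `X`).
#' @param g A [gap_model()].
#' @return A list with `score` (non-negative integer), `query_end` and
#'   `subject_end` (1-based residue indices of the maximal cell, `NA` when
#'   the score is 0 or a sequence is empty).
#' @export
local_alignment_score <- function(a, b, m, g = gap_model()) {
  stopifnot(is.matrix(m), inherits(g, "gap_model"))
  av <- letters_to_matrix_idx(a, m)
  bv <- letters_to_matrix_idx(b, m)
  res <- .gotoh_score(av, bv, m, g$gap_open, g$gap_extend)
  if (res$score == 0L) {
    res$query_end <- NA_integer_
    res$subject_end <- NA_integer_
  }
  res
}

# Normalize a residue string and map it to 0-based scoring-matrix row
# indices; empty input gives an empty vector.
letters_to_matrix_idx <- function(x, m) {
  if (is.null(x) || !nzchar(x)) return(integer(0))
  ch <- strsplit(normalize_letters(x), "", fixed = TRUE)[[1]]
  idx <- match(ch, rownames(m))
  if (anyNA(idx))
    stop("scoring matrix lacks letter(s): ",
         paste(unique(ch[is.na(idx)]), collapse = ", "))
  idx - 1L
}

#' Does an alignment clear the score threshold?
#'
#' The search default of 80 (with BLOSUM62) separates relevant from spurious
#' local alignments; raw substitution-matrix scores are compared, not
#' bitscores or E-values.
#'
#' @param r An alignment result from [local_alignment_score()].
#' @param threshold Non-negative integer score threshold.
#' @return `TRUE` iff `r$score >= threshold`.
#' @export
score_passes <- function(r, threshold = 80L) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  r$score >= threshold
}
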