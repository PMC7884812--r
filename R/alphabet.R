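#' Default amino-acid frequency table
#'
#' Background residue frequencies used both for alphabet clustering and for
#' sampling synthetic proteins. Values follow the UniProtKB/Swiss-Prot
#' residue composition statistics, with tryptophan at 1.0% and cysteine at
#' 1.3% -- the two rarest residues, which drives the first cluster merge.
#' Frequencies cover the 20 standard amino acids only (`X` never takes part
#' in merging) and are normalized to sum to 1.
#'
#' @return A named numeric vector over the 20 standard amino acids.
#' @export
default_frequency_table <- function() {
  f <- c(A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0130,
         Q = 0.0393, E = 0.0672, G = 0.0707, H = 0.0227, I = 0.0591,
         L = 0.0965, K = 0.0580, M = 0.0241, F = 0.0386, P = 0.0474,
         S = 0.0663, T = 0.0535, W = 0.0100, Y = 0.0292, V = 0.0686)
  # keep the W/C anchors exact; rescale the rest to close the sum at 1
  others <- setdiff(names(f), c("W", "C"))
  f[others] <- f[others] * (1 - f[["W"]] - f[["C"]]) / sum(f[others])
  f[order(names(f))]
}

#' Read a residue-frequency table from a two-column text file
#'
#' Each non-comment line holds a residue letter and its fraction, whitespace
#' or tab separated. The 20 standard amino acids must all be present;
#' fractions are normalized to sum to 1.
#'
#' @param path Path to the table file.
#' @return A named numeric vector over the 20 standard amino acids.
#' @export
read_frequency_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("letter", "fraction"),
                           colClasses = c("character", "numeric"))
  f <- stats::setNames(tab$fraction, toupper(tab$letter))
  validate_frequency_table(f)
}

validate_frequency_table <- function(f) {
  aa20 <- setdiff(PROTEIN_ALPHABET, "X")
  if (!all(aa20 %in% names(f)))
    stop("frequency table missing residue(s): ",
         paste(setdiff(aa20, names(f)), collapse = ", "))
  f <- f[aa20]
  if (any(!is.finite(f)) || any(f <= 0))
    stop("frequency table values must be positive")
  f / sum(f)
}

#' Build a reduced amino-acid alphabet by agglomerative merging
#'
#' Starting from 21 singleton clusters (20 standard amino acids plus `X`),
#' the two non-`X` clusters with the smallest summed frequency are merged
#' repeatedly until `k` clusters remain. The representative of a merged
#' cluster is its most frequent member letter (ties broken alphabetically);
#' `X` is never merged and always represents itself. With the default table,
#' `k = 21` is the identity map and `k = 20` merges exactly tryptophan and
#' cysteine, the two rarest residues.
#'
#' Reduced alphabets are applied to the *filter stage only*: they coarsen
#' the 4-mer letter comparison (raising filter sensitivity), while local
#' alignment always scores original residues with the unmodified matrix.
#'
#' @param freqs Named numeric frequency vector over the 20 standard amino
#'   acids, e.g. [default_frequency_table()].
#' @param k Target alphabet size, between 15 and 21.
#' @return An object of class `cluster_map`: a list with `k`, `rep` (named
#'   character, letter to representative letter), `members` (representative
#'   to member letters), `codes` (letter to integer code of its
#'   representative) and `signature`.
#' @export
build_cluster_map <- function(freqs = default_frequency_table(), k = 21L) {
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) ||
      k < 15L || k > 21L)
    stop("cluster size k must be an integer in [15, 21]")
  k <- as.integer(k)
  freqs <- validate_frequency_table(freqs)

  # clusters as lists of member letters, kept sorted for determinism
  clusters <- lapply(names(freqs), identity)
  for (step in seq_len(21L - k)) {
    totals <- vapply(clusters, function(cl) sum(freqs[cl]), numeric(1))
    nc <- length(clusters)
    best <- NULL
    best_sum <- Inf
    for (i in seq_len(nc - 1L)) {
      for (j in seq.int(i + 1L, nc)) {
        s <- totals[i] + totals[j]
        if (s < best_sum - 1e-15) {
          best_sum <- s
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }

  rep_of <- character(0)
  members <- list()
  for (cl in clusters) {
    f <- freqs[cl]
    r <- sort(cl[f == max(f)])[[1]]  # most frequent member; ties alphabetical
    rep_of[cl] <- r
    members[[r]] <- cl
  }
  rep_of["X"] <- "X"
  members[["X"]] <- "X"
  members <- members[order(names(members))]
  codes <- stats::setNames(match(rep_of[PROTEIN_ALPHABET], PROTEIN_ALPHABET) - 1L,
                           PROTEIN_ALPHABET)
  structure(
    list(k = k, rep = rep_of[PROTEIN_ALPHABET], members = members,
         codes = codes,
         signature = paste0("k", k, ":", paste(rep_of[PROTEIN_ALPHABET],
                                               collapse = ""))),
    class = "cluster_map"
  )
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map k=%d>\n", x$k))
  merged <- Filter(function(m) length(m) > 1L, x$members)
  if (length(merged) == 0L) {
    cat("  identity (no merged clusters)\n")
  } else {
    for (r in names(merged))
      cat(sprintf("  %s <- {%s}\n", r, paste(merged[[r]], collapse = ", ")))
  }
  invisible(x)
}

#' Assert that alignment scoring ignores alphabet clustering
#'
#' Reduced alphabets coarsen only the filter's 4-mer comparison; the
#' Smith-Waterman stage always scores the original residues with the
#' original, uncollapsed matrix. This guard encodes that engine contract:
#' it returns the matrix unchanged for any cluster map.
#'
#' @param cmap A cluster map (unused beyond validation).
#' @param m A scoring matrix from [parse_score_matrix()].
#' @return `m`, unchanged.
#' @export
collapse_matrix_check <- function(cmap, m) {
  stopifnot(inherits(cmap, "cluster_map"), is.matrix(m))
  m
}
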