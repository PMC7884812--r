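# Independent brute-force oracles. These deliberately avoid the package's
# packed-integer and compiled code paths: the filter oracle works on
# character substrings, the alignment oracle is a plain O(MN) dynamic
# program in R.

STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# normalization mirror (kept separate from the package implementation)
oracle_normalize <- function(letters) {
  x <- strsplit(toupper(letters), "", fixed = TRUE)[[1]]
  x[!(x %in% c(STANDARD_AA, "X"))] <- "X"
  x
}

# rewrite letters to their cluster representatives at the character level
oracle_apply_cmap <- function(letters, cmap) {
  x <- oracle_normalize(letters)
  paste0(unname(cmap$rep[x]), collapse = "")
}

# string-search every query 4-mer among the subject's 4-mers taken at
# stride `step` (1 = full mode, 2 = fast mode)
oracle_match_vector <- function(qletters, sletters, step = 1L) {
  q <- paste0(oracle_normalize(qletters), collapse = "")
  s <- paste0(oracle_normalize(sletters), collapse = "")
  M <- nchar(q)
  N <- nchar(s)
  if (M < 4L) return(logical(0))
  starts <- if (N >= 4L) seq.int(1L, N - 3L, by = step) else integer(0)
  subj_kmers <- substring(s, starts, starts + 3L)
  q_starts <- seq_len(M - 3L)
  substring(q, q_starts, q_starts + 3L) %in% subj_kmers
}

# sliding-window popcount over all windows of <= 16 consecutive positions
oracle_window_pass <- function(bits, n) {
  for (i in seq_along(bits)) {
    if (sum(bits[max(1L, i - 15L):i]) > n)
      return(list(passed = TRUE, first_pass_index = i))
  }
  list(passed = FALSE, first_pass_index = NA_integer_)
}

oracle_filter <- function(qletters, sletters, n, step = 1L) {
  oracle_window_pass(oracle_match_vector(qletters, sletters, step), n)
}

# naive full-matrix Gotoh DP; gap of length L costs open + (L-1)*extend
oracle_gotoh <- function(a, b, m, open, extend) {
  A <- oracle_normalize(a)
  B <- oracle_normalize(b)
  M <- length(A)
  N <- length(B)
  if (M == 0L || N == 0L)
    return(list(score = 0L, query_end = NA_integer_, subject_end = NA_integer_))
  NEG <- -1e9
  H <- matrix(0, M + 1L, N + 1L)
  E <- matrix(NEG, M + 1L, N + 1L)
  F <- matrix(NEG, M + 1L, N + 1L)
  best <- 0
  bi <- NA_integer_
  bj <- NA_integer_
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - open, E[i + 1L, j] - extend)
      F[i + 1L, j + 1L] <- max(H[i, j + 1L] - open, F[i, j + 1L] - extend)
      h <- max(0, H[i, j] + m[A[[i]], B[[j]]],
               E[i + 1L, j + 1L], F[i + 1L, j + 1L])
      H[i + 1L, j + 1L] <- h
      if (h > best) {
        best <- h
        bi <- i
        bj <- j
      }
    }
  }
  list(score = as.integer(best), query_end = bi, subject_end = bj)
}

# ungapped self-alignment score: sum of diagonal matrix entries
oracle_self_score <- function(letters, m) {
  x <- oracle_normalize(letters)
  sum(m[cbind(x, x)])
}
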