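# residues sampled i.i.d. from a frequency table under the current RNG state
random_letters <- function(length, freqs) {
  paste0(sample(names(freqs), length, replace = TRUE, prob = freqs),
         collapse = "")
}

#' Generate a random protein sequence
#'
#' Residues are drawn i.i.d. from the frequency table with a seeded
#' generator, so the same `(length, freqs, seed)` always yields the same
#' sequence. The calling session's RNG state is left untouched.
#'
#' @param length Sequence length, at least 1.
#' @param freqs Residue-frequency table, e.g. [default_frequency_table()].
#' @param seed Integer seed.
#' @param id Record id.
#' @return A one-row protein record data.frame (`id`, `description`,
#'   `letters`).
#' @export
random_protein <- function(length, freqs = default_frequency_table(),
                           seed = 1L, id = "random") {
  if (!is.numeric(length) || length < 1)
    stop("length must be at least 1")
  freqs <- validate_frequency_table(freqs)
  letters <- withr::with_seed(seed, random_letters(as.integer(length), freqs))
  data.frame(id = id, description = "synthetic random protein",
             letters = letters, stringsAsFactors = FALSE)
}

#' Specification of a planted homolog
#'
#' Describes how a subject sequence is derived from a query: a segment of
#' the query is copied into the subject at `copy_start` (1-based), given
#' `substitutions` point mutations, and embedded in random flanks up to
#' `subject_length`.
#'
#' @param query_id,subject_id Record ids.
#' @param copy_start 1-based subject offset of the planted segment.
#' @param segment_length Length of the copied query segment.
#' @param substitutions Number of point mutations applied to the copy, in
#'   \[0, segment_length\].
#' @param subject_length Total subject length; the planted segment must lie
#'   fully inside the subject.
#' @param seed Integer seed for flank generation and mutation placement.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(query_id, subject_id, copy_start, segment_length,
                       substitutions = 0L, subject_length, seed = 1L) {
  stopifnot(is.numeric(copy_start), copy_start >= 1,
            is.numeric(segment_length), segment_length >= 1,
            is.numeric(subject_length), subject_length >= 1)
  if (substitutions < 0 || substitutions > segment_length)
    stop("substitutions must be in [0, segment_length]")
  if (copy_start + segment_length - 1 > subject_length)
    stop("planted segment must lie fully inside the subject")
  structure(
    list(query_id = query_id, subject_id = subject_id,
         copy_start = as.integer(copy_start),
         segment_length = as.integer(segment_length),
         substitutions = as.integer(substitutions),
         subject_length = as.integer(subject_length),
         seed = as.integer(seed)),
    class = "plant_spec"
  )
}

# mutate `k` distinct positions of `segment`, never to the original letter
mutate_segment <- function(segment, k, freqs) {
  if (k == 0L) return(segment)
  chars <- strsplit(segment, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    alt <- freqs[names(freqs) != chars[[p]]]
    chars[[p]] <- sample(names(alt), 1L, prob = alt)
  }
  paste0(chars, collapse = "")
}

#' Plant a mutated copy of a query segment into a random subject
#'
#' Builds a subject consisting of random flanks around a copy of a query
#' segment carrying exactly `spec$substitutions` seeded point mutations at
#' distinct positions (never mutating a residue to itself). The segment's
#' start within the query is drawn at random (seeded). With zero
#' substitutions and a segment of length at least `n + 4`, the planted
#' subject is guaranteed to pass the full-mode filter at nearby threshold
#' `n`.
#'
#' @param query A protein record (list or one-row data.frame with `id`,
#'   `letters`).
#' @param spec A [plant_spec()].
#' @param freqs Residue-frequency table for flanks and mutations.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A list with `record` (the subject, one-row data.frame) and
#'   `truth` (a one-row data.frame: `query_id`, `subject_id`, `query_start`,
#'   `copy_start`, `segment_length`, `substitutions`).
#' @export
plant_homolog <- function(query, spec, freqs = default_frequency_table(),
                          seed = spec$seed) {
  stopifnot(inherits(spec, "plant_spec"))
  freqs <- validate_frequency_table(freqs)
  m <- nchar(query$letters)
  if (spec$segment_length > m)
    stop("segment_length exceeds query length")
  withr::with_seed(seed, {
    qstart <- sample(m - spec$segment_length + 1L, 1L)
    segment <- substr(query$letters, qstart, qstart + spec$segment_length - 1L)
    segment <- mutate_segment(segment, spec$substitutions, freqs)
    left <- spec$copy_start - 1L
    right <- spec$subject_length - (spec$copy_start + spec$segment_length - 1L)
    letters <- paste0(
      if (left > 0L) random_letters(left, freqs) else "",
      segment,
      if (right > 0L) random_letters(right, freqs) else "")
    list(
      record = data.frame(id = spec$subject_id,
                          description = "synthetic planted homolog",
                          letters = letters, stringsAsFactors = FALSE),
      truth = data.frame(query_id = spec$query_id,
                         subject_id = spec$subject_id,
                         query_start = qstart,
                         copy_start = spec$copy_start,
                         segment_length = spec$segment_length,
                         substitutions = spec$substitutions,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Generate a synthetic benchmark database with planted homologs
#'
#' Writes a query FASTA, a database FASTA and a truth TSV listing the
#' planted (query, subject) pairs. `n_planted` queries are generated with
#' lengths drawn uniformly from `length_range`; each is planted into one
#' subject according to `spec_template`, and the remaining subjects are
#' unrelated random proteins. With the default exact-copy template
#' (`segment_length = NULL`, `substitutions = 0`) each planted subject is a
#' verbatim copy of its query, so a default search recovers every truth row
#' whose ungapped self-score reaches the score threshold. Everything is a
#' pure function of `seed`: reruns produce byte-identical files.
#'
#' The default length range 100--400 brackets the typical protein length in
#' curated databases (averages around 360 residues).
#'
#' @param n_subjects Total database size.
#' @param n_planted Number of planted homologs (and of queries).
#' @param length_range Length bounds `c(min, max)` for queries and subjects.
#' @param spec_template List with `segment_length` (`NULL` for a full exact
#'   copy of the query) and `substitutions`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param freqs Residue-frequency table.
#' @return Invisibly, a list with `query_path`, `db_path`, `truth_path`, and
#'   the in-memory `queries`, `db` and `truth` tables.
#' @export
make_benchmark_db <- function(n_subjects = 500L, n_planted = 20L,
                              length_range = c(100L, 400L),
                              spec_template = list(segment_length = NULL,
                                                   substitutions = 0L),
                              seed = 42L, dir = tempfile("fourmer_bench_"),
                              freqs = default_frequency_table()) {
  stopifnot(n_planted <= n_subjects, n_planted >= 0,
            length(length_range) == 2L, length_range[1] <= length_range[2])
  freqs <- validate_frequency_table(freqs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subs <- spec_template$substitutions %||% 0L
  seg <- spec_template$segment_length

  gen <- withr::with_seed(seed, {
    qlen <- sample(seq.int(length_range[1], length_range[2]), n_planted,
                   replace = TRUE)
    queries <- data.frame(
      id = sprintf("Q%04d", seq_len(max(n_planted, 0L))),
      description = "synthetic query",
      letters = vapply(qlen, random_letters, character(1), freqs = freqs),
      stringsAsFactors = FALSE)

    planted_at <- sort(sample(n_subjects, n_planted))
    subj_ids <- sprintf("S%04d", seq_len(n_subjects))
    letters <- character(n_subjects)
    truth <- vector("list", n_planted)
    for (i in seq_len(n_planted)) {
      si <- planted_at[[i]]
      q <- queries[i, ]
      if (is.null(seg)) {
        # exact-template default: the subject is a verbatim copy of the query
        sl <- nchar(q$letters)
        sp <- plant_spec(q$id, subj_ids[[si]], copy_start = 1L,
                         segment_length = sl, substitutions = subs,
                         subject_length = sl,
                         seed = sample.int(2^30, 1L))
      } else {
        sl <- max(sample(seq.int(length_range[1], length_range[2]), 1L),
                  seg)
        sp <- plant_spec(q$id, subj_ids[[si]],
                         copy_start = sample(sl - seg + 1L, 1L),
                         segment_length = seg, substitutions = subs,
                         subject_length = sl,
                         seed = sample.int(2^30, 1L))
      }
      ph <- plant_homolog(q, sp, freqs)
      letters[[si]] <- ph$record$letters
      truth[[i]] <- ph$truth
    }
    filler <- setdiff(seq_len(n_subjects), planted_at)
    for (si in filler)
      letters[[si]] <- random_letters(
        sample(seq.int(length_range[1], length_range[2]), 1L), freqs)
    db <- data.frame(id = subj_ids, description = "synthetic subject",
                     letters = letters, stringsAsFactors = FALSE)
    list(queries = queries, db = db,
         truth = if (n_planted > 0L) do.call(rbind, truth) else
           data.frame(query_id = character(0), subject_id = character(0),
                      query_start = integer(0), copy_start = integer(0),
                      segment_length = integer(0), substitutions = integer(0)))
  })

  query_path <- file.path(dir, "queries.fasta")
  db_path <- file.path(dir, "db.fasta")
  truth_path <- file.path(dir, "truth.tsv")
  write_fasta(gen$queries, query_path)
  write_fasta(gen$db, db_path)
  utils::write.table(gen$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(query_path = query_path, db_path = db_path,
                 truth_path = truth_path, queries = gen$queries,
                 db = gen$db, truth = gen$truth))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
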