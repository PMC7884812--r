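#' Search parameters
#'
#' Bundles every knob of the two-stage search. Defaults follow the tool's
#' standard operating point: nearby threshold 3 (four 4-mer matches within a
#' 16-residue query window), no alphabet reduction (`cluster = 21`),
#' exhaustive filtering, score threshold 80 with BLOSUM62, and gap penalties
#' 11/1.
#'
#' @param nearby Nearby threshold `n` in \[1, 15\]; a subject passes the
#'   filter when some 16-position query window holds more than `n` matches.
#' @param cluster Reduced-alphabet size in \[15, 21\]; 21 disables reduction.
#'   Applied to the filter stage only.
#' @param fast Logical; index subject 4-mers at even offsets only
#'   (non-exhaustive mode).
#' @param score_threshold Minimum raw alignment score for a hit.
#' @param gap A [gap_model()].
#' @param workers Number of parallel workers scanning the database.
#' @param batch_size Subjects claimed per work unit; 10 balances worker
#'   contention against load balance.
#' @param matrix Scoring matrix: a path to an NCBI-format file or a parsed
#'   matrix.
#' @param freqs Residue-frequency table used to build the cluster map.
#' @return An object of class `search_params`.
#' @export
search_params <- function(nearby = 3L, cluster = 21L, fast = FALSE,
                          score_threshold = 80L, gap = gap_model(),
                          workers = default_workers(), batch_size = 10L,
                          matrix = blosum62_path(),
                          freqs = default_frequency_table()) {
  if (!is.numeric(nearby) || nearby < 1 || nearby > 15)
    stop("nearby threshold must be an integer in [1, 15]")
  if (!is.numeric(cluster) || cluster < 15 || cluster > 21)
    stop("cluster size must be an integer in [15, 21]")
  if (!is.numeric(workers) || workers < 1) stop("workers must be >= 1")
  if (!is.numeric(batch_size) || batch_size < 1) stop("batch_size must be >= 1")
  if (!is.numeric(score_threshold) || score_threshold < 0)
    stop("score_threshold must be >= 0")
  structure(
    list(nearby = as.integer(nearby), cluster = as.integer(cluster),
         fast = isTRUE(fast), score_threshold = as.integer(score_threshold),
         gap = gap, workers = as.integer(workers),
         batch_size = as.integer(batch_size), matrix = matrix, freqs = freqs),
    class = "search_params"
  )
}

#' @rdname search_params
#' @export
default_workers <- function() {
  n <- tryCatch(parallel::detectCores(logical = TRUE), error = function(e) 1L)
  if (is.na(n) || n < 1L) 1L else as.integer(n)
}

#' Search protein queries against a protein database
#'
#' The database is encoded once under the cluster map and its 4-mers packed
#' once up front; queries are then processed one after another. For every
#' (query, subject) pair the subject is aligned iff it passes the 4-mer
#' nearby filter, and a hit is emitted iff the alignment score reaches the
#' threshold. Alignment always scores original residues with the unmodified
#' matrix, whatever the cluster setting.
#'
#' Work is distributed to workers in contiguous batches of
#' `params$batch_size` subjects, but the output is *independent* of
#' `workers` and `batch_size`: hits are sorted by (query input order,
#' descending score, subject id) before return. Database packing time is
#' excluded from the throughput metric.
#'
#' @param queries,db Data frames of protein records, as from [read_fasta()].
#' @param params A [search_params()] object.
#' @return A list of class `fourmer_search` with `hits` (data.frame:
#'   `query_id`, `subject_id`, `score`, `query_end`, `subject_end`) and
#'   `metrics` (list: `pairs_examined`, `pairs_filtered_out`,
#'   `pairs_aligned`, `cell_updates`, `elapsed_seconds`, `gcups`).
#' @export
search <- function(queries, db, params = search_params()) {
  stopifnot(inherits(params, "search_params"))
  if (!is.data.frame(queries) || nrow(queries) == 0L)
    stop("query set is empty")
  if (!is.data.frame(db) || nrow(db) == 0L)
    stop("database is empty")

  m <- if (is.matrix(params$matrix)) params$matrix
       else parse_score_matrix(params$matrix)
  cmap <- build_cluster_map(params$freqs, params$cluster)
  m <- collapse_matrix_check(cmap, m)

  # one-off database preparation, excluded from the throughput metric
  db_codes <- lapply(seq_len(nrow(db)), function(i) {
    build_kmer_codes(encode_sequence(db[i, ], cmap), fast = params$fast)
  })
  db_idx <- lapply(seq_len(nrow(db)), function(i)
    letters_to_matrix_idx(db$letters[[i]], m))
  batches <- split(seq_len(nrow(db)),
                   ceiling(seq_len(nrow(db)) / params$batch_size))

  t0 <- proc.time()[["elapsed"]]
  n_aligned <- 0L
  cell_updates <- 0
  all_hits <- vector("list", nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    q_enc <- encode_sequence(queries[qi, ], cmap)
    q_idx <- letters_to_matrix_idx(queries$letters[[qi]], m)
    scan_batch <- function(batch) {
      hits <- list()
      aligned <- 0L
      cells <- 0
      for (si in batch) {
        dec <- filter_subject(q_enc, db_codes[[si]], params$nearby)
        if (!dec$passed) next
        aligned <- aligned + 1L
        cells <- cells + as.numeric(length(q_idx)) * length(db_idx[[si]])
        r <- .gotoh_score(q_idx, db_idx[[si]], m, params$gap$gap_open,
                          params$gap$gap_extend)
        if (r$score >= params$score_threshold) {
          hits[[length(hits) + 1L]] <- data.frame(
            query_id = queries$id[[qi]], subject_id = db$id[[si]],
            score = r$score, query_end = r$query_end,
            subject_end = r$subject_end, stringsAsFactors = FALSE)
        }
      }
      list(hits = hits, aligned = aligned, cells = cells)
    }
    res <- if (params$workers > 1L)
      parallel::mclapply(batches, scan_batch, mc.cores = params$workers)
    else
      lapply(batches, scan_batch)
    for (b in res) {
      n_aligned <- n_aligned + b$aligned
      cell_updates <- cell_updates + b$cells
    }
    qh <- do.call(rbind, unlist(lapply(res, `[[`, "hits"), recursive = FALSE))
    all_hits[[qi]] <- qh
  }
  elapsed <- proc.time()[["elapsed"]] - t0

  hits <- do.call(rbind, Filter(Negate(is.null), all_hits))
  if (is.null(hits))
    hits <- data.frame(query_id = character(0), subject_id = character(0),
                       score = integer(0), query_end = integer(0),
                       subject_end = integer(0), stringsAsFactors = FALSE)
  # deterministic output contract: query input order, score desc, subject id
  ord <- order(match(hits$query_id, queries$id), -hits$score, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL

  pairs <- nrow(queries) * nrow(db)
  metrics <- list(
    pairs_examined = pairs,
    pairs_filtered_out = pairs - n_aligned,
    pairs_aligned = n_aligned,
    cell_updates = cell_updates,
    elapsed_seconds = elapsed,
    gcups = if (elapsed > 0) cell_updates / elapsed / 1e9 else NA_real_
  )
  structure(list(hits = hits, metrics = metrics), class = "fourmer_search")
}

#' @export
print.fourmer_search <- function(x, ...) {
  cat(sprintf(
    "<fourmer_search: %d hits; %d pairs examined, %d aligned (%.1f%% filtered out); %.3f GCUPS>\n",
    nrow(x$hits), x$metrics$pairs_examined, x$metrics$pairs_aligned,
    100 * x$metrics$pairs_filtered_out / max(x$metrics$pairs_examined, 1L),
    x$metrics$gcups))
  invisible(x)
}

#' Write hits to a tab-separated file
#'
#' One row per hit with columns `query_id`, `subject_id`, `score`,
#' `query_end`, `subject_end`; the header line is prefixed with `#`. Row
#' order is preserved from [search()].
#'
#' @param hits Hit data.frame from [search()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("query_id", "subject_id", "score", "query_end", "subject_end")
  stopifnot(is.data.frame(hits), all(cols %in% names(hits)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(hits) > 0L)
    utils::write.table(hits[, cols], con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[[1]], "#"))
    stop("not a hits TSV: missing '#' header in '", path, "'")
  cols <- strsplit(sub("^#", "", lines[[1]]), "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  if (length(body) == 0L) {
    out <- data.frame(query_id = character(0), subject_id = character(0),
                      score = integer(0), query_end = integer(0),
                      subject_end = integer(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- utils::read.table(text = body, sep = "\t", col.names = cols,
                           stringsAsFactors = FALSE)
  out$score <- as.integer(out$score)
  out$query_end <- as.integer(out$query_end)
  out$subject_end <- as.integer(out$subject_end)
  out
}

#' Command-line entry point
#'
#' Thin wrapper over [search()] (and, with the leading argument `generate`,
#' over [make_benchmark_db()]). Intended to be called from a shell via
#' `Rscript -e 'quit(status = fourmer::run_cli())'` or the bundled script
#' `inst/scripts/fourmer`.
#'
#' Search flags: `-q/--query`, `-d/--db`, `-o/--out` (required), `-n`
#' nearby threshold, `-c` cluster size, `-f` fast mode, `-p` workers,
#' `--batch-size`, `--matrix`, `--score-threshold`, `--gap-open`,
#' `--gap-extend`, `--freq-table`, `--verbose`. Counts and GCUPS are logged
#' to stderr on completion. Behavior is fully deterministic; no seed is
#' consumed.
#'
#' @param argv Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Exit code, invisibly: 0 on success, 2 on usage errors, 1 on
#'   runtime errors.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) >= 1L && identical(argv[[1]], "generate"))
    return(invisible(cli_generate(argv[-1])))
  invisible(cli_search(argv))
}

cli_search <- function(argv) {
  opts <- list(
    optparse::make_option(c("-q", "--query"), type = "character",
                          help = "query FASTA file [required]"),
    optparse::make_option(c("-d", "--db"), type = "character",
                          help = "database FASTA file [required]"),
    optparse::make_option(c("-o", "--out"), type = "character",
                          help = "output hits TSV [required]"),
    optparse::make_option(c("-n", "--nearby"), type = "integer", default = 3L,
                          help = "nearby threshold [default %default]"),
    optparse::make_option(c("-c", "--cluster"), type = "integer", default = 21L,
                          help = "reduced alphabet size [default %default]"),
    optparse::make_option(c("-f", "--fast"), action = "store_true",
                          default = FALSE,
                          help = "non-exhaustive mode (even subject offsets)"),
    optparse::make_option(c("-p", "--workers"), type = "integer",
                          default = default_workers(),
                          help = "parallel workers [default: all cores]"),
    optparse::make_option("--batch-size", type = "integer", default = 10L,
                          dest = "batch_size",
                          help = "subjects per work unit [default %default]"),
    optparse::make_option("--matrix", type = "character",
                          default = blosum62_path(),
                          help = "scoring matrix file [default: BLOSUM62]"),
    optparse::make_option("--score-threshold", type = "integer", default = 80L,
                          dest = "score_threshold",
                          help = "minimum hit score [default %default]"),
    optparse::make_option("--gap-open", type = "integer", default = 11L,
                          dest = "gap_open",
                          help = "gap open cost [default %default]"),
    optparse::make_option("--gap-extend", type = "integer", default = 1L,
                          dest = "gap_extend",
                          help = "gap extension cost [default %default]"),
    optparse::make_option("--freq-table", type = "character", default = NULL,
                          dest = "freq_table",
                          help = "two-column residue frequency table"),
    optparse::make_option(c("-v", "--verbose"), action = "store_true",
                          default = FALSE, help = "log per-query progress")
  )
  parser <- optparse::OptionParser(
    usage = "fourmer -q query.fasta -d db.fasta -o hits.tsv [options]",
    option_list = opts)
  o <- tryCatch(optparse::parse_args(parser, args = argv),
                error = function(e) e)
  if (inherits(o, "error")) {
    message("fourmer: ", conditionMessage(o))
    return(2L)
  }
  if (is.null(o$query) || is.null(o$db) || is.null(o$out)) {
    message("fourmer: missing required flag(s); -q, -d and -o are required")
    message(paste(utils::capture.output(optparse::print_help(parser)),
                  collapse = "\n"))
    return(2L)
  }
  code <- tryCatch({
    freqs <- if (is.null(o$freq_table)) default_frequency_table()
             else read_frequency_table(o$freq_table)
    params <- search_params(
      nearby = o$nearby, cluster = o$cluster, fast = o$fast,
      score_threshold = o$score_threshold,
      gap = gap_model(o$gap_open, o$gap_extend),
      workers = o$workers, batch_size = o$batch_size,
      matrix = o$matrix, freqs = freqs)
    queries <- read_fasta(o$query)
    db <- read_fasta(o$db)
    if (o$verbose)
      message(sprintf("fourmer: %d queries vs %d subjects (n=%d, c=%d%s)",
                      nrow(queries), nrow(db), params$nearby, params$cluster,
                      if (params$fast) ", fast" else ""))
    res <- search(queries, db, params)
    write_hits_tsv(res$hits, o$out)
    mt <- res$metrics
    message(sprintf(
      "fourmer: %d hits; %d pairs examined, %d filtered out, %d aligned; %.3f GCUPS",
      nrow(res$hits), mt$pairs_examined, mt$pairs_filtered_out,
      mt$pairs_aligned, mt$gcups))
    0L
  }, error = function(e) {
    message("fourmer: error: ", conditionMessage(e))
    1L
  })
  code
}

cli_generate <- function(argv) {
  opts <- list(
    optparse::make_option("--out-dir", type = "character", dest = "out_dir",
                          help = "output directory [required]"),
    optparse::make_option("--n-subjects", type = "integer", default = 500L,
                          dest = "n_subjects"),
    optparse::make_option("--n-planted", type = "integer", default = 20L,
                          dest = "n_planted"),
    optparse::make_option("--min-length", type = "integer", default = 100L,
                          dest = "min_length"),
    optparse::make_option("--max-length", type = "integer", default = 400L,
                          dest = "max_length"),
    optparse::make_option("--segment-length", type = "integer", default = NULL,
                          dest = "segment_length",
                          help = "planted segment length [default: full query copy]"),
    optparse::make_option("--substitutions", type = "integer", default = 0L),
    optparse::make_option("--seed", type = "integer", default = 42L)
  )
  parser <- optparse::OptionParser(
    usage = "fourmer generate --out-dir DIR [options]", option_list = opts)
  o <- tryCatch(optparse::parse_args(parser, args = argv),
                error = function(e) e)
  if (inherits(o, "error")) {
    message("fourmer generate: ", conditionMessage(o))
    return(2L)
  }
  if (is.null(o$out_dir)) {
    message("fourmer generate: --out-dir is required")
    return(2L)
  }
  tryCatch({
    paths <- make_benchmark_db(
      n_subjects = o$n_subjects, n_planted = o$n_planted,
      length_range = c(o$min_length, o$max_length),
      spec_template = list(segment_length = o$segment_length,
                           substitutions = o$substitutions),
      seed = o$seed, dir = o$out_dir)
    message(sprintf("fourmer generate: wrote %s, %s, %s",
                    paths$query_path, paths$db_path, paths$truth_path))
    0L
  }, error = function(e) {
    message("fourmer generate: error: ", conditionMessage(e))
    1L
  })
}
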