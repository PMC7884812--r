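small_bench <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_benchmark_db(n_subjects = 60L, n_planted = 5L,
                                  seed = 404L)
    cache
  }
})

test_that("every query recovers its exact database copy at its self-score", {
  b <- small_bench()
  res <- fourmer::search(b$queries, b$db, search_params(workers = 1L))
  for (i in seq_len(nrow(b$truth))) {
    tr <- b$truth[i, ]
    row <- res$hits[res$hits$query_id == tr$query_id &
                    res$hits$subject_id == tr$subject_id, ]
    expect_identical(nrow(row), 1L, label = tr$query_id)
    qseq <- b$queries$letters[b$queries$id == tr$query_id]
    expect_identical(row$score, as.integer(oracle_self_score(qseq, blosum62)))
  }
})

test_that("search equals the sequential filter/align/threshold composition", {
  b <- small_bench()
  params <- search_params(workers = 2L, batch_size = 7L)
  res <- fourmer::search(b$queries, b$db, params)
  cmap <- build_cluster_map(k = 21L)
  expected <- list()
  for (qi in seq_len(nrow(b$queries))) {
    q <- b$queries[qi, ]
    eq <- encode_sequence(q, cmap)
    for (si in seq_len(nrow(b$db))) {
      s <- b$db[si, ]
      kc <- build_kmer_codes(encode_sequence(s, cmap), fast = FALSE)
      if (!filter_subject(eq, kc, 3L)$passed) next
      r <- local_alignment_score(q$letters, s$letters, blosum62, gap_model())
      if (score_passes(r, 80L))
        expected[[length(expected) + 1L]] <-
          data.frame(query_id = q$id, subject_id = s$id, score = r$score,
                     query_end = r$query_end, subject_end = r$subject_end,
                     stringsAsFactors = FALSE)
    }
  }
  expected <- do.call(rbind, expected)
  expected <- expected[order(match(expected$query_id, b$queries$id),
                             -expected$score, expected$subject_id), ]
  rownames(expected) <- NULL
  expect_identical(res$hits, expected)
})

test_that("hit lists are identical across workers and batch sizes", {
  b <- small_bench()
  ref <- NULL
  for (w in c(1L, 2L)) {
    for (bs in c(1L, 7L, 50L)) {
      res <- fourmer::search(b$queries, b$db,
                             search_params(workers = w, batch_size = bs))
      if (is.null(ref)) ref <- res$hits
      else expect_identical(res$hits, ref,
                            label = sprintf("workers=%d batch=%d", w, bs))
    }
  }
})

test_that("metrics conserve pair counts and measure aligned cells", {
  b <- small_bench()
  res <- fourmer::search(b$queries, b$db, search_params(workers = 1L))
  mt <- res$metrics
  expect_identical(mt$pairs_examined, nrow(b$queries) * nrow(b$db))
  expect_identical(mt$pairs_examined, mt$pairs_filtered_out + mt$pairs_aligned)
  expect_gte(mt$pairs_aligned, nrow(b$truth))
  expect_gt(mt$cell_updates, 0)
})

test_that("degenerate searches error cleanly", {
  b <- small_bench()
  none <- b$queries[0, ]
  expect_error(fourmer::search(none, b$db), "empty")
  expect_error(fourmer::search(b$queries, b$db[0, ]), "empty")
  expect_error(search_params(nearby = 0L), "\\[1, 15\\]")
  expect_error(search_params(cluster = 14L), "\\[15, 21\\]")
  expect_error(search_params(batch_size = 0L), "batch_size")
})

test_that("hits TSV round-trips and degenerates to a header-only file", {
  b <- small_bench()
  res <- fourmer::search(b$queries, b$db, search_params(workers = 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(res$hits, path)
  lines <- readLines(path)
  expect_true(startsWith(lines[[1]], "#query_id\tsubject_id"))
  expect_length(lines, nrow(res$hits) + 1L)
  expect_identical(read_hits_tsv(path), res$hits)

  empty_path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(res$hits[0, ], empty_path)
  expect_length(readLines(empty_path), 1L)
  expect_identical(nrow(read_hits_tsv(empty_path)), 0L)
})

test_that("the CLI wires defaults and matches the in-process API", {
  b <- small_bench()
  out <- withr::local_tempfile(fileext = ".tsv")
  code <- run_cli(c("-q", b$query_path, "-d", b$db_path, "-o", out,
                    "-p", "2")) |> suppressMessages()
  expect_identical(code, 0L)
  api <- fourmer::search(read_fasta(b$query_path), read_fasta(b$db_path),
                         search_params(workers = 2L))
  expect_identical(read_hits_tsv(out), api$hits)

  # explicit flags equal the API with those parameters
  out2 <- withr::local_tempfile(fileext = ".tsv")
  code2 <- run_cli(c("-q", b$query_path, "-d", b$db_path, "-o", out2,
                     "-n", "3", "-c", "21", "-f", "-p", "4")) |>
    suppressMessages()
  expect_identical(code2, 0L)
  api2 <- fourmer::search(read_fasta(b$query_path), read_fasta(b$db_path),
                          search_params(fast = TRUE, workers = 4L))
  expect_identical(read_hits_tsv(out2), api2$hits)
})

test_that("the CLI rejects bad parameters and missing flags", {
  b <- small_bench()
  out <- withr::local_tempfile(fileext = ".tsv")
  expect_identical(
    suppressMessages(run_cli(c("-q", b$query_path, "-d", b$db_path,
                               "-o", out, "-n", "0"))), 1L)
  expect_identical(suppressMessages(run_cli(character(0))), 2L)
  expect_identical(suppressMessages(run_cli(c("-q", b$query_path))), 2L)
})
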