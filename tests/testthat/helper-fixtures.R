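# shared fixtures built in code at test time

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tmp_matrix <- function(lines) {
  path <- withr::local_tempfile(fileext = ".mat",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# 3-letter toy matrix: +1 on the diagonal, -1 off it
toy_matrix_lines <- c(
  "# toy 3-letter matrix",
  "   A  C  D",
  "A  1 -1 -1",
  "C -1  1 -1",
  "D -1 -1  1"
)

blosum62 <- fourmer::parse_score_matrix(fourmer::blosum62_path())
identity_cmap <- fourmer::build_cluster_map(k = 21L)

random_record <- function(len, seed, id = paste0("r", seed)) {
  fourmer::random_protein(len, seed = seed, id = id)
}

# the shared fixed benchmark used by engine/acceptance tests
fixture_bench <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- fourmer::make_benchmark_db(n_subjects = 500L, n_planted = 20L,
                                           seed = 20260923L)
    cache
  }
})

hit_keys <- function(hits) paste(hits$query_id, hits$subject_id, hits$score)
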