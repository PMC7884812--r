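enc <- function(letters, cmap = identity_cmap, id = "s")
  encode_sequence(list(id = id, letters = letters), cmap)

test_that("pack_4mer is positional and bijective", {
  expect_identical(pack_4mer(c(0L, 0L, 0L, 0L)), 0)
  expect_false(pack_4mer(c(1L, 0L, 0L, 0L)) == pack_4mer(c(0L, 0L, 0L, 1L)))

  # brute-force enumeration over a 5-letter toy alphabet: all codes distinct
  tuples <- expand.grid(0:4, 0:4, 0:4, 0:4)
  packed <- apply(as.matrix(tuples), 1L, pack_4mer)
  expect_length(unique(packed), 5L^4L)

  expect_error(pack_4mer(c(1L, 2L, 3L)), "exactly 4")
  expect_error(pack_4mer(c(0L, 0L, 0L, 300L)), "\\[0, 255\\]")
})

test_that("build_kmer_codes counts offsets for both strides", {
  s4 <- enc("ACDE")
  expect_length(build_kmer_codes(s4)$codes, 1L)

  s9 <- enc("ACDEFGHIK")
  expect_length(build_kmer_codes(s9, fast = FALSE)$codes, 6L)
  fast9 <- build_kmer_codes(s9, fast = TRUE)
  expect_length(fast9$codes, 3L)  # offsets 0, 2, 4
  expect_identical(fast9$codes,
                   build_kmer_codes(s9, fast = FALSE)$codes[c(1L, 3L, 5L)])

  s3 <- enc("ACD")
  expect_length(build_kmer_codes(s3, fast = FALSE)$codes, 0L)
  expect_length(build_kmer_codes(s3, fast = TRUE)$codes, 0L)

  # count formulas across lengths
  for (len in 4:40) {
    s <- enc(random_record(len, seed = len)$letters)
    expect_length(build_kmer_codes(s, fast = FALSE)$codes, len - 3L)
    expect_length(build_kmer_codes(s, fast = TRUE)$codes,
                  floor((len - 4L) / 2L) + 1L)
  }
})

test_that("match_vector agrees with a substring-search oracle", {
  q <- enc("ACDEACDE", id = "q")
  expect_true(all(match_vector(q, build_kmer_codes(q))))

  no_a_run <- enc(strrep("AC", 20L))
  expect_false(any(match_vector(enc(strrep("A", 10L), id = "q"),
                                build_kmer_codes(no_a_run))))

  for (trial in 1:100) {
    qr <- random_record(60, seed = 1000 + trial, id = "q")
    sr <- random_record(300, seed = 2000 + trial, id = "s")
    got <- match_vector(enc(qr$letters, id = "q"),
                        build_kmer_codes(enc(sr$letters)))
    expect_identical(got, oracle_match_vector(qr$letters, sr$letters))
  }
})

test_that("match_vector rejects mixed cluster maps and short queries", {
  k20 <- build_cluster_map(k = 20L)
  q <- enc("ACDEACDE", id = "q")
  s20 <- build_kmer_codes(enc("ACDEACDE", cmap = k20))
  expect_error(match_vector(q, s20), "different cluster maps")
  expect_length(match_vector(enc("ACD", id = "q"),
                             build_kmer_codes(enc("ACDEACDE"))), 0L)
})

test_that("nearby_pass implements the strict 16-window popcount rule", {
  # four matches inside one 16-position window beat n = 3
  mv <- rep(FALSE, 40L)
  mv[c(3L, 7L, 11L, 15L)] <- TRUE
  d <- nearby_pass(mv, 3L)
  expect_true(d$passed)
  expect_identical(d$first_pass_index, 15L)
  # exactly n matches never pass (strictly greater required)
  mv3 <- rep(FALSE, 40L)
  mv3[c(3L, 7L, 11L)] <- TRUE
  expect_false(nearby_pass(mv3, 3L)$passed)

  expect_false(nearby_pass(rep(FALSE, 50L), 1L)$passed)

  # isolated matches 20 positions apart never give 2 in a 16-window
  sparse <- rep(FALSE, 70L)
  sparse[c(1L, 21L, 41L, 61L)] <- TRUE
  expect_false(nearby_pass(sparse, 1L)$passed)

  expect_error(nearby_pass(mv, 0L), "\\[1, 15\\]")
  expect_error(nearby_pass(mv, 16L), "\\[1, 15\\]")
})

test_that("nearby_pass equals the sliding-window oracle on random vectors", {
  set.seed(77)
  for (trial in 1:60) {
    bits <- runif(sample(1:80, 1L)) < 0.25
    for (n in c(1L, 3L, 5L, 8L)) {
      expect_identical(nearby_pass(bits, n), oracle_window_pass(bits, n),
                       label = sprintf("trial %d n %d", trial, n))
    }
  }
})

test_that("raising the threshold only flips decisions pass -> fail", {
  set.seed(42)
  for (trial in 1:30) {
    bits <- runif(60) < 0.3
    passes <- vapply(1:15, function(n) nearby_pass(bits, n)$passed, logical(1))
    expect_true(all(diff(passes) <= 0))  # monotone non-increasing in n
  }
})

test_that("filter_subject composes matching and the nearby window", {
  qr <- random_record(50, seed = 31, id = "q")
  self <- filter_subject(enc(qr$letters, id = "q"),
                         build_kmer_codes(enc(qr$letters)), 3L)
  expect_true(self$passed)

  # degenerate inputs fail silently
  expect_false(filter_subject(enc("ACD", id = "q"),
                              build_kmer_codes(enc("ACDEACDE")), 3L)$passed)
  expect_false(filter_subject(enc("ACDEACDE", id = "q"),
                              build_kmer_codes(enc("ACD")), 3L)$passed)
})

test_that("a planted exact substring of length n + 4 guarantees a pass", {
  set.seed(11)
  for (trial in 1:40) {
    n <- ((trial - 1L) %% 8L) + 1L
    q <- random_record(60, seed = 500 + trial, id = "q")
    sp <- plant_spec("q", "s", copy_start = sample(1:120, 1L),
                     segment_length = n + 4L, substitutions = 0L,
                     subject_length = 160L, seed = 600 + trial)
    subj <- plant_homolog(q, sp)$record
    dec <- filter_subject(enc(q$letters, id = "q"),
                          build_kmer_codes(enc(subj$letters)), n)
    expect_true(dec$passed, label = sprintf("trial %d (n=%d)", trial, n))
  }
})

test_that("fast-mode passes imply full-mode passes", {
  set.seed(12)
  hits <- 0L
  for (trial in 1:60) {
    q <- random_record(40, seed = 900 + trial, id = "q")
    sp <- plant_spec("q", "s", copy_start = sample(1:60, 1L),
                     segment_length = sample(8:20, 1L), substitutions = 0L,
                     subject_length = 100L, seed = 950 + trial)
    subj <- plant_homolog(q, sp)$record
    e_q <- enc(q$letters, id = "q")
    e_s <- enc(subj$letters)
    for (n in c(1L, 3L, 5L)) {
      fast_pass <- filter_subject(e_q, build_kmer_codes(e_s, fast = TRUE), n)$passed
      full_pass <- filter_subject(e_q, build_kmer_codes(e_s, fast = FALSE), n)$passed
      if (fast_pass) {
        hits <- hits + 1L
        expect_true(full_pass)
      }
    }
  }
  expect_gt(hits, 0L)  # the implication was actually exercised
})

test_that("coarser cluster maps never destroy a filter pass", {
  maps <- lapply(21:15, function(k) build_cluster_map(k = k))
  for (trial in 1:25) {
    q <- random_record(50, seed = 1300 + trial, id = "q")
    sp <- plant_spec("q", "s", copy_start = 10L, segment_length = 10L,
                     substitutions = 2L, subject_length = 120L,
                     seed = 1350 + trial)
    subj <- plant_homolog(q, sp)$record
    passes <- vapply(maps, function(cm) {
      filter_subject(encode_sequence(q, cm),
                     build_kmer_codes(encode_sequence(subj, cm)), 3L)$passed
    }, logical(1))
    expect_true(all(diff(passes) >= 0))  # monotone as k decreases
  }
})

test_that("padded block count matches the 512-bit comparison formula", {
  N <- 4:10000
  expect_identical(ceiling((N - 3) / 16), ceiling((4 * N - 12) / 64))
})
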