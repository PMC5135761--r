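relaxed <- stemloop_params(min_stem = 3, max_stem = 6, max_loop = 5,
                           max_mismatch = 0)

test_that("a planted perfect hairpin is located at its loop", {
  h <- find_stem_loop_at("GGGCAAAAGCCC", 5, 8, relaxed)
  expect_identical(nrow(h), 1L)
  expect_identical(h$left_start, 1L)
  expect_identical(h$left_end, 4L)
  expect_identical(h$right_start, 9L)
  expect_identical(h$right_end, 12L)
  expect_identical(h$penalty, 0L)
})

test_that("homopolymers yield no stem anywhere", {
  expect_null(find_stem_loop_at("AAAAAAAAAAAA", 5, 8, relaxed))
  expect_identical(nrow(scan_stemloops("AAAAAAAAAAAA", relaxed)), 0L)
})

test_that("loop spans outside the sequence or bounds are errors", {
  expect_error(find_stem_loop_at("GGGCAAAAGCCC", 11, 15, relaxed),
               "out of bounds")
  expect_error(find_stem_loop_at("GGGCAAAAGCCC", 5, 11, relaxed),
               "loop length")
})

test_that("the 12-bp hairpin yields exactly one deduplicated hit", {
  h <- scan_stemloops("GGGCAAAAGCCC", relaxed)
  expect_identical(nrow(h), 1L)
  expect_identical(h$left_start, 1L)
  expect_identical(h$right_end, 12L)
})

test_that("sequences shorter than a minimal hairpin give an empty table", {
  h <- scan_stemloops(strrep("A", 20))  # default params need >= 33 bp
  expect_s3_class(h, "stemloop_hits")
  expect_identical(nrow(h), 0L)
})

test_that("scan output matches the exhaustive oracle on random sequences", {
  set.seed(201)
  cols <- c("left_start", "left_end", "loop_start", "loop_end",
            "right_start", "right_end", "stem_len", "penalty", "events")
  for (rep in 1:12) {
    p <- stemloop_params(min_stem = sample(2:4, 1),
                         max_stem = sample(c(4, 6, 8), 1),
                         max_loop = sample(c(3, 6), 1),
                         max_mismatch = sample(0:2, 1))
    s <- random_seq(sample(30:60, 1))
    got <- as.data.frame(scan_stemloops(s, p))
    want <- oracle_scan(s, p)
    expect_identical(nrow(got), nrow(want), info = s)
    if (nrow(got))
      expect_equal(got[, cols], want[, cols], ignore_attr = TRUE)
  }
})

test_that("relaxing constraints never removes a hit locus", {
  set.seed(202)
  for (rep in 1:8) {
    s <- random_seq(100)
    base <- stemloop_params(min_stem = 4, max_stem = 6, max_loop = 5,
                            max_mismatch = 1)
    h0 <- scan_stemloops(s, base)
    loci0 <- paste(h0$left_end, h0$right_start)
    for (wider in list(
      stemloop_params(min_stem = 4, max_stem = 6, max_loop = 5,
                      max_mismatch = 2),
      stemloop_params(min_stem = 4, max_stem = 6, max_loop = 7,
                      max_mismatch = 1),
      stemloop_params(min_stem = 4, max_stem = 9, max_loop = 5,
                      max_mismatch = 1))) {
      h1 <- scan_stemloops(s, wider)
      expect_true(all(loci0 %in% paste(h1$left_end, h1$right_start)))
    }
  }
})

test_that("any planted perfect inverted repeat is reported with penalty 0", {
  set.seed(203)
  for (rep in 1:10) {
    stem <- sample(5:9, 1); loop <- sample(3:6, 1)
    hp <- make_hairpin(hairpin_spec(stem, loop), seed = rep)
    p <- stemloop_params(min_stem = stem, max_stem = stem,
                         max_loop = loop, max_mismatch = 0)
    h <- as.data.frame(scan_stemloops(hp$sequence, p))
    tr <- hp$truth
    match_row <- h$left_start == tr$left_start & h$left_end == tr$left_end &
      h$right_start == tr$right_start & h$right_end == tr$right_end &
      h$penalty == 0
    expect_true(any(match_row), info = hp$sequence)
  }
})

test_that("hits on the reverse complement mirror the forward hits", {
  set.seed(204)
  p <- stemloop_params(min_stem = 4, max_stem = 8, max_loop = 6,
                       max_mismatch = 2)
  for (rep in 1:10) {
    s <- random_seq(150)
    hf <- as.data.frame(scan_stemloops(s, p))
    hr <- as.data.frame(scan_stemloops(reverse_complement(s), p))
    key <- function(d) sort(paste(d$left_start, d$left_end, d$loop_start,
                                  d$loop_end, d$right_start, d$right_end,
                                  d$penalty))
    expect_identical(key(mirror_spans(hf, 150)), key(hr), info = s)
  }
})

test_that("every reported penalty respects the mismatch budget", {
  set.seed(205)
  for (mm in 0:2) {
    p <- stemloop_params(min_stem = 3, max_stem = 6, max_loop = 6,
                         max_mismatch = mm)
    h <- scan_stemloops(random_seq(200), p)
    expect_true(all(h$penalty <= mm))
    expect_true(all(h$stem_len >= 3))
    expect_true(all(h$loop_len >= p$min_loop & h$loop_len <= p$max_loop))
  }
})

test_that("named vectors and record data frames scan identically", {
  seqs <- c(x1 = "GGGCAAAAGCCC", x2 = strrep("T", 12))
  df <- data.frame(id = names(seqs), sequence = unname(seqs))
  expect_identical(as.data.frame(scan_stemloops(seqs, relaxed)),
                   as.data.frame(scan_stemloops(df, relaxed)))
  expect_identical(scan_stemloops(seqs, relaxed)$seq_id, "x1")
  # case-insensitive scanning
  expect_identical(
    as.data.frame(scan_stemloops("gggcaaaagccc", relaxed))[, -1],
    as.data.frame(scan_stemloops("GGGCAAAAGCCC", relaxed))[, -1])
})
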