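test_that("hairpin specs validate their geometry", {
  expect_error(hairpin_spec(stem_len = 0), "stem_len")
  expect_error(hairpin_spec(10, 5, bulge_offset = 10,
                            bulge_sizes = c(1, 0)), "bulge_offset")
  expect_error(hairpin_spec(10, 5, bulge_offset = 4), "bulge_sizes are 0")
  expect_error(hairpin_spec(10, 5, bulge_sizes = c(1, 0)),
               "without a bulge_offset")
  expect_error(hairpin_spec(10, 5, gc_fraction = 1.2), "gc_fraction")
})

test_that("a generated perfect hairpin is recovered exactly", {
  sp <- hairpin_spec(10, 5)
  hp <- make_hairpin(sp, seed = 7)
  expect_identical(nchar(hp$sequence), 25L)
  p <- stemloop_params(min_stem = 10, max_stem = 10, max_loop = 5,
                       max_mismatch = 0)
  h <- as.data.frame(scan_stemloops(hp$sequence, p))
  tr <- hp$truth
  found <- h$left_start == tr$left_start & h$left_end == tr$left_end &
    h$loop_start == tr$loop_start & h$loop_end == tr$loop_end &
    h$right_start == tr$right_start & h$right_end == tr$right_end &
    h$penalty == 0
  expect_true(any(found))
})

test_that("a planted bulge appears as a single gap event at its rung", {
  sp <- hairpin_spec(10, 5, bulge_offset = 4, bulge_sizes = c(1, 0))
  hp <- make_hairpin(sp, seed = 7)
  expect_identical(nchar(hp$sequence), 26L)
  h <- scan_stemloops(hp$sequence, params_for_hairpin(sp))
  h <- h[h$loop_start == hp$truth$loop_start &
           h$loop_end == hp$truth$loop_end, ]
  expect_identical(nrow(h), 1L)
  ev <- strsplit(h$events[1], "")[[1]]
  expect_identical(sum(ev == "B"), 1L)
  expect_identical(sum(ev == "A"), 0L)
  expect_identical(sum(ev == "M"), 0L)
  # the gap sits after 4 pair rungs counting from the loop
  expect_identical(which(ev == "B"), 5L)
  expect_identical(h$penalty[1], 1L)
})

test_that("generation is a deterministic function of the seed", {
  sp <- hairpin_spec(12, 6, bulge_offset = 5, bulge_sizes = c(0, 1))
  expect_identical(make_hairpin(sp, seed = 99), make_hairpin(sp, seed = 99))
  expect_false(make_hairpin(sp, seed = 99)$sequence ==
                 make_hairpin(sp, seed = 100)$sequence)
  f1 <- make_family(template_len = 120, n_copies = 6,
                    spec = hairpin_spec(8, 4), sub_rate = 0.05, seed = 12)
  f2 <- make_family(template_len = 120, n_copies = 6,
                    spec = hairpin_spec(8, 4), sub_rate = 0.05, seed = 12)
  expect_identical(f1, f2)
})

test_that("unmutated families reproduce the planted fraction exactly", {
  fam <- make_family(template_len = 300, n_copies = 40,
                     spec = hairpin_spec(15, 6), plant_rel_pos = 0.9,
                     plant_fraction = 0.75, sub_rate = 0, seed = 1)
  expect_identical(nrow(fam$records), 40L)
  expect_identical(nrow(fam$truth), 30L)
  p <- params_for_hairpin(hairpin_spec(15, 6))
  hits <- scan_stemloops(fam$records, p)
  lens <- stats::setNames(nchar(fam$records$sequence), fam$records$id)
  cp <- coverage_profile(hits, lens)
  expect_equal(max(cp$value), 0.75)
  tr <- fam$truth[1, ]
  planted_bins <- unique(floor(((tr$left_start:tr$right_end) - 1) *
                                 100 / 300) + 1)
  expect_true(all(cp$value[planted_bins] == 0.75))
  expect_true(all(cp$value[-planted_bins] == 0))
  # every carrier yields its planted hit at the exact truth spans
  key <- function(d) paste(d$seq_id, d$left_start, d$left_end,
                           d$loop_start, d$loop_end, d$right_start,
                           d$right_end)
  expect_true(all(key(fam$truth) %in% key(as.data.frame(hits))))
})

test_that("plant_fraction 0 gives a flat zero profile", {
  fam <- make_family(template_len = 300, n_copies = 10,
                     spec = hairpin_spec(15, 6), plant_fraction = 0,
                     sub_rate = 0, seed = 2)
  expect_identical(nrow(fam$truth), 0L)
  p <- params_for_hairpin(hairpin_spec(15, 6))
  hits <- scan_stemloops(fam$records, p)
  expect_identical(nrow(hits), 0L)
  lens <- stats::setNames(nchar(fam$records$sequence), fam$records$id)
  expect_true(all(coverage_profile(hits, lens)$value == 0))
})

test_that("increasing substitution rates degrade the peak monotonically", {
  p <- params_for_hairpin(hairpin_spec(15, 6))
  peaks <- vapply(c(0, 0.05, 0.1, 0.2, 0.3), function(rate) {
    fam <- make_family(template_len = 300, n_copies = 20,
                       spec = hairpin_spec(15, 6), plant_fraction = 0.8,
                       sub_rate = rate, seed = 21)
    hits <- scan_stemloops(fam$records, p)
    lens <- stats::setNames(nchar(fam$records$sequence), fam$records$id)
    max(coverage_profile(hits, lens)$value)
  }, numeric(1))
  expect_identical(peaks[1], 0.8)
  expect_true(all(diff(peaks) <= 0))
})

test_that("invalid generator arguments are rejected", {
  expect_error(make_family(plant_fraction = 1.5), "plant_")
  expect_error(make_family(sub_rate = -0.1), "sub_rate")
  expect_error(make_family(template_len = 20, spec = hairpin_spec(15, 6)),
               "does not fit")
})
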