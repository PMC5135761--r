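# two 100-bp sequences sharing a perfect hairpin at positions 51-62
hairpin_at_51 <- function() {
  paste0(strrep("A", 50), "GGGCAAAAGCCC", strrep("A", 38))
}
relaxed <- stemloop_params(min_stem = 3, max_stem = 6, max_loop = 5,
                           max_mismatch = 0)

test_that("coverage is 1.0 where every sequence carries the hit", {
  seqs <- c(s1 = hairpin_at_51(), s2 = hairpin_at_51())
  hits <- scan_stemloops(seqs, relaxed)
  cp <- coverage_profile(hits, c(s1 = 100, s2 = 100))
  expect_identical(attr(cp, "n_sequences"), 2L)
  expect_true(all(cp$value[51:62] == 1.0))
  expect_true(all(cp$value[-(51:62)] == 0))
})

test_that("coverage is 0.5 when one of two sequences carries the hit", {
  seqs <- c(s1 = hairpin_at_51(), s2 = strrep("A", 100))
  hits <- scan_stemloops(seqs, relaxed)
  cp <- coverage_profile(hits, c(s1 = 100, s2 = 100))
  expect_true(all(cp$value[51:62] == 0.5))
  expect_true(all(cp$value[-(51:62)] == 0))
})

test_that("bases map to bins by floor(i * n_bins / L)", {
  # 10-bin profile of a 100-bp sequence: base 51-62 -> bins 6 and 7
  seqs <- c(s1 = hairpin_at_51())
  hits <- scan_stemloops(seqs, relaxed)
  cp <- coverage_profile(hits, c(s1 = 100), n_bins = 10)
  expect_identical(which(cp$value > 0), c(6L, 7L))
  # per-base mode requires equal lengths
  expect_identical(sum(coverage_profile(hits, c(s1 = 100),
                                        n_bins = NULL)$value), 12)
  expect_error(coverage_profile(hits, c(s1 = 100, s2 = 90), n_bins = NULL),
               "equal-length")
})

test_that("coverage is invariant under family duplication", {
  fam <- make_family(template_len = 200, n_copies = 10,
                     spec = hairpin_spec(8, 4), plant_rel_pos = 0.5,
                     plant_fraction = 0.6, sub_rate = 0, seed = 9)
  p <- params_for_hairpin(hairpin_spec(8, 4))
  hits <- scan_stemloops(fam$records, p)
  lens <- stats::setNames(nchar(fam$records$sequence), fam$records$id)
  cp1 <- coverage_profile(hits, lens)
  dup <- fam$records
  dup$id <- paste0(dup$id, "_b")
  hits2 <- scan_stemloops(rbind(fam$records, dup), p)
  lens2 <- c(lens, stats::setNames(lens, paste0(names(lens), "_b")))
  cp2 <- coverage_profile(hits2, lens2)
  expect_equal(cp1$value, cp2$value)
})

test_that("bin mass is conserved and order-independent", {
  fam <- make_family(template_len = 150, n_copies = 8,
                     spec = hairpin_spec(8, 4), plant_rel_pos = 0.3,
                     plant_fraction = 0.5, sub_rate = 0, seed = 10)
  p <- params_for_hairpin(hairpin_spec(8, 4))
  hits <- scan_stemloops(fam$records, p)
  lens <- stats::setNames(nchar(fam$records$sequence), fam$records$id)
  cp <- coverage_profile(hits, lens)
  # sum of value * n equals the number of (sequence, covered-bin) incidences
  incid <- 0
  for (id in names(lens)) {
    h <- hits[hits$seq_id == id, , drop = FALSE]
    if (!nrow(h)) next
    covered <- logical(lens[[id]])
    for (k in seq_len(nrow(h)))
      covered[h$left_start[k]:h$right_end[k]] <- TRUE
    incid <- incid +
      length(unique(floor((which(covered) - 1) * 100 / lens[[id]]) + 1))
  }
  expect_equal(sum(cp$value) * attr(cp, "n_sequences"), incid)
  # permuting the hit rows changes nothing
  perm <- hits[sample(nrow(hits)), ]
  expect_equal(coverage_profile(perm, lens)$value, cp$value)
  expect_equal(coverage_profile(hits, rev(lens))$value, cp$value)
})

test_that("an empty family is an error", {
  h <- scan_stemloops("GGGCAAAAGCCC", relaxed)
  expect_error(coverage_profile(h, integer(0)), "empty family")
  expect_error(coverage_profile(h, c(10, 20)), "named")
  expect_error(coverage_profile(h, c(other = 100)), "absent")
})

test_that("perfect stems give an all-zero stem-anchored profile", {
  st <- parse_dot_bracket("GGGGTTTTCCCC", "((((....))))")
  pp <- pairing_profile(rep(list(st), 5), mode = "from_loop")
  expect_identical(attr(pp, "n_structures"), 5L)
  expect_true(all(pp$count == 0))
})

test_that("a single 3'-arm interruption lands three rungs from the loop", {
  st <- parse_dot_bracket("GGGGGGAAAACCCTCCC", "((((((....))).)))")
  pp <- pairing_profile(list(st), mode = "from_loop", arms = "combined")
  expect_identical(pp$count[pp$offset == 3], 1L)
  expect_true(all(pp$count[pp$offset != 3] == 0))
  per <- pairing_profile(list(st), mode = "from_loop", arms = "per_arm")
  expect_identical(per$right[per$offset == 3], 1L)
  expect_true(all(per$left == 0))
})

test_that("planted bulge offsets are recovered exactly in the profile", {
  offsets <- rep(3:8, length.out = 20)
  structures <- lapply(seq_along(offsets), function(k) {
    side <- if (k %% 2 == 0) c(1L, 0L) else c(0L, 1L)
    sp <- hairpin_spec(10, 5, bulge_offset = offsets[k], bulge_sizes = side)
    hp <- make_hairpin(sp, seed = 400 + k)
    h <- scan_stemloops(hp$sequence, params_for_hairpin(sp))
    hit_to_structure(h[1, ], hp$sequence)
  })
  pp <- pairing_profile(structures, mode = "from_loop")
  want <- table(factor(offsets, levels = pp$offset))
  expect_identical(pp$count, as.integer(want))
})

test_that("unsupported structures are rejected", {
  no_pairs <- parse_dot_bracket("ACGT", "....")
  expect_error(pairing_profile(list(no_pairs)), "zero pairs")
  multi <- parse_dot_bracket("GCAAAGCGCAAAGC", "((...))((...))")
  expect_error(pairing_profile(list(multi)), "exactly one")
})

test_that("normalised profiles count unpaired-in-bin structures", {
  st <- parse_dot_bracket("GGGGTTTTCCCC", "((((....))))")
  pp <- pairing_profile(list(st, st), mode = "normalized_100")
  expect_identical(nrow(pp), 100L)
  # loop bases 5-8 of 12 land in bins floor((i-1)*100/12)+1 = 34, 42, 51, 59
  expect_identical(which(pp$count > 0), c(34L, 42L, 51L, 59L))
  expect_true(all(pp$count[pp$count > 0] == 2))
  # permutation invariance
  st2 <- parse_dot_bracket("GGGGGGAAAACCCTCCC", "((((((....))).)))")
  a <- pairing_profile(list(st, st2), mode = "from_loop")
  b <- pairing_profile(list(st2, st), mode = "from_loop")
  expect_identical(a$count, b$count)
})
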