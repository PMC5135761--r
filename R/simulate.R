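#' Specification of a planted hairpin
#'
#' Describes the geometry of a hairpin to be generated by [make_hairpin()]
#' or planted into a family by [make_family()]. The default geometry
#' (10 bp stem, 5 bp loop) follows the consensus stem-loop reported for
#' young transposon subfamilies: a 5-7 bp loop on an 8-10 bp stem, with an
#' optional bulge a few rungs from the loop.
#'
#' @param stem_len Stem length in base pairs (rungs).
#' @param loop_len Loop length in bases.
#' @param bulge_offset Optional distance of a planted bulge from the loop,
#'   in stem rungs; must satisfy `1 <= bulge_offset < stem_len`.
#' @param bulge_sizes Integer pair: number of unpaired bases inserted at
#'   the bulge position into the 5' and 3' arm respectively.
#' @param gc_fraction GC content of the generated arms and loop.
#' @return An object of class `hairpin_spec`.
#' @examples
#' hairpin_spec(stem_len = 10, loop_len = 5, bulge_offset = 4,
#'              bulge_sizes = c(1, 0))
#' @export
hairpin_spec <- function(stem_len = 10L, loop_len = 5L, bulge_offset = NULL,
                         bulge_sizes = c(0L, 0L), gc_fraction = 0.5) {
  stem_len <- as.integer(stem_len); loop_len <- as.integer(loop_len)
  if (stem_len < 1L) stop("stem_len must be >= 1")
  if (loop_len < 1L) stop("loop_len must be >= 1")
  bulge_sizes <- as.integer(bulge_sizes)
  if (length(bulge_sizes) != 2L || any(bulge_sizes < 0L))
    stop("bulge_sizes must be two non-negative integers")
  if (!is.null(bulge_offset)) {
    bulge_offset <- as.integer(bulge_offset)
    if (bulge_offset < 1L || bulge_offset >= stem_len)
      stop("need 1 <= bulge_offset < stem_len")
    if (sum(bulge_sizes) == 0L)
      stop("bulge_offset given but both bulge_sizes are 0")
  } else if (sum(bulge_sizes) > 0L) {
    stop("bulge_sizes given without a bulge_offset")
  }
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must lie in [0, 1]")
  structure(list(stem_len = stem_len, loop_len = loop_len,
                 bulge_offset = bulge_offset, bulge_sizes = bulge_sizes,
                 gc_fraction = gc_fraction),
            class = "hairpin_spec")
}

#' Geometry-matched search parameters for a planted hairpin
#'
#' Derives the most stringent [stemloop_params()] under which a hairpin
#' generated from `spec` is still found exactly: stems clamped to the
#' planted stem length (plus any bulge insertion on the arm windows), loops
#' spanning the planted loop length, and a mismatch budget equal to the
#' total planted bulge size. Under these settings a scan of a generated
#' family recovers exactly the planted structures -- chance hits are
#' (astronomically) unlikely and the budget-driven arm extension that a
#' generous `max_mismatch` produces cannot occur.
#'
#' @param spec A [hairpin_spec()].
#' @return A [stemloop_params()].
#' @examples
#' params_for_hairpin(hairpin_spec(15, 6))
#' @export
params_for_hairpin <- function(spec) {
  stopifnot(inherits(spec, "hairpin_spec"))
  stemloop_params(
    min_stem = spec$stem_len,
    max_stem = spec$stem_len + max(spec$bulge_sizes),
    max_loop = spec$loop_len,
    min_loop = min(3L, spec$loop_len),
    max_mismatch = sum(spec$bulge_sizes))
}

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

# a random base whose complement is in neither of `avoid`
base_avoiding_pairing <- function(avoid) {
  ok <- BASES[!(COMP[BASES] %in% toupper(avoid))]
  sample(ok, 1L)
}

#' Generate a single hairpin sequence with known geometry
#'
#' Draws a random left arm at the requested GC content, sets the right arm
#' to its reverse complement, and joins them with a random loop whose
#' terminal bases are chosen not to pair with each other (so the planted
#' stem cannot silently grow into the loop). If a bulge is specified, the
#' extra bases are inserted between stem rungs `bulge_offset - 1` and
#' `bulge_offset` (counting from the loop, loop-closing rung = rung 0) and
#' are chosen not to pair with the bases facing them across the stem.
#'
#' @param spec A [hairpin_spec()].
#' @param seed Integer seed; the output is a deterministic function of
#'   `(spec, seed)`.
#' @param seq_id Identifier recorded in the truth table.
#' @return A list with elements `sequence` and `truth`, the latter a
#'   one-row data frame with the planted 1-based spans (`left_start`,
#'   `left_end`, `loop_start`, `loop_end`, `right_start`, `right_end`),
#'   the geometry, and comma-separated absolute `bulge_positions`.
#' @examples
#' hp <- make_hairpin(hairpin_spec(stem_len = 10, loop_len = 5), seed = 7)
#' nchar(hp$sequence)  # 25
#' @export
make_hairpin <- function(spec = hairpin_spec(), seed = 1L,
                         seq_id = "hairpin") {
  stopifnot(inherits(spec, "hairpin_spec"))
  with_seed(seed, {
    left <- strsplit(random_dna(spec$stem_len, spec$gc_fraction),
                     "")[[1]]
    right <- unname(COMP[rev(left)])
    loop <- strsplit(random_dna(spec$loop_len, spec$gc_fraction), "")[[1]]
    # terminal loop bases must not pair with each other
    if (spec$loop_len >= 2L) {
      while (COMP[loop[1]] == loop[spec$loop_len])
        loop[spec$loop_len] <- sample(BASES, 1L)
    }
    bulge_pos <- integer(0)
    if (!is.null(spec$bulge_offset)) {
      k <- spec$bulge_offset
      s <- spec$stem_len
      # left-arm insertion sits between left[s-k] and left[s-k+1];
      # right-arm insertion between right[k] and right[k+1]
      lb <- if (spec$bulge_sizes[1] > 0L)
        vapply(seq_len(spec$bulge_sizes[1]), function(i)
          base_avoiding_pairing(right[c(k, k + 1L)]), character(1))
      else character(0)
      rb <- if (spec$bulge_sizes[2] > 0L)
        vapply(seq_len(spec$bulge_sizes[2]), function(i)
          base_avoiding_pairing(left[c(s - k, s - k + 1L)]), character(1))
      else character(0)
      left2 <- append(left, lb, after = s - k)
      right2 <- append(right, rb, after = k)
      nl <- length(left2)
      if (length(lb))
        bulge_pos <- c(bulge_pos, (s - k + 1L):(s - k + length(lb)))
      if (length(rb))
        bulge_pos <- c(bulge_pos,
                       nl + spec$loop_len + k + seq_along(rb))
      left <- left2; right <- right2
    }
    seq <- paste(c(left, loop, right), collapse = "")
    nl <- length(left)
    truth <- data.frame(
      seq_id = seq_id,
      left_start = 1L, left_end = nl,
      loop_start = nl + 1L, loop_end = nl + spec$loop_len,
      right_start = nl + spec$loop_len + 1L,
      right_end = nl + spec$loop_len + length(right),
      stem_len = spec$stem_len, loop_len = spec$loop_len,
      bulge_offset = if (is.null(spec$bulge_offset)) NA_integer_
                     else spec$bulge_offset,
      bulge_positions = paste(bulge_pos, collapse = ","),
      stringsAsFactors = FALSE)
    list(sequence = seq, truth = truth)
  })
}

#' Simulate a transposon-like sequence family with a planted hairpin
#'
#' Emulates a transposon subfamily: `n_copies` mutated copies of one random
#' template, with the hairpin described by `spec` written over the template
#' at a conserved relative position in a `plant_fraction` share of the
#' copies. Substitutions are applied i.i.d. at `sub_rate` per base over the
#' whole copy (hairpin included), mirroring how stem-loops decay in aging
#' subfamilies; because the mutation model is substitution-only, the
#' planted truth spans remain exact at every rate.
#'
#' The template is rejection-sampled so that, under `check_params`, it
#' contains no stem-loop of its own; coverage outside the planted region
#' is then exactly zero for unmutated families.
#'
#' @param template_len Template (and copy) length in bp.
#' @param n_copies Number of family members.
#' @param spec A [hairpin_spec()] for the planted hairpin.
#' @param plant_rel_pos Relative start position of the hairpin in the copy,
#'   as a fraction of its length (clamped so the hairpin fits).
#' @param plant_fraction Fraction of copies carrying the hairpin; the
#'   carrier count is `round(plant_fraction * n_copies)`, and carriers are
#'   drawn at random.
#' @param sub_rate Per-base substitution probability.
#' @param seed Integer seed; all randomness flows from it.
#' @param check_params A [stemloop_params()] used for the template
#'   cleanliness check (default: the geometry-matched
#'   [params_for_hairpin()] settings), or `NULL` to skip the check.
#'   Stem-loop searches run with a generous mismatch budget (such as the
#'   transposon-annotation defaults of [stemloop_params()]) will report
#'   chance hits on any random template; the cleanliness guarantee only
#'   applies to scans at the stringency of `check_params`.
#' @return A list with `records` (data frame `id`/`sequence`), `truth`
#'   (one row per planted copy, absolute 1-based spans) and `template`.
#' @examples
#' fam <- make_family(template_len = 300, n_copies = 8,
#'                    spec = hairpin_spec(15, 6), plant_rel_pos = 0.9,
#'                    plant_fraction = 0.75, sub_rate = 0, seed = 1)
#' nrow(fam$truth)  # 6 carriers
#' @export
make_family <- function(template_len = 300L, n_copies = 40L,
                        spec = hairpin_spec(15L, 6L),
                        plant_rel_pos = 0.9, plant_fraction = 0.75,
                        sub_rate = 0, seed = 1L,
                        check_params = params_for_hairpin(spec)) {
  template_len <- as.integer(template_len)
  stopifnot(inherits(spec, "hairpin_spec"))
  if (plant_rel_pos < 0 || plant_rel_pos > 1 ||
      plant_fraction < 0 || plant_fraction > 1)
    stop("plant_rel_pos and plant_fraction must lie in [0, 1]")
  if (sub_rate < 0 || sub_rate > 1) stop("sub_rate must lie in [0, 1]")
  hp <- make_hairpin(spec, seed = seed + 1L)
  hp_len <- nchar(hp$sequence)
  if (hp_len > template_len)
    stop("hairpin (", hp_len, " bp) does not fit the template (",
         template_len, " bp)")
  with_seed(seed, {
    template <- NULL
    for (try in seq_len(100L)) {
      cand <- random_dna(template_len)
      if (is.null(check_params) ||
          nrow(scan_stemloops(cand, check_params)) == 0L) {
        template <- cand
        break
      }
    }
    if (is.null(template))
      stop("could not draw a template free of accidental stem-loops in ",
           "100 attempts; relax 'check_params' or change the seed")
    start <- min(max(1L, as.integer(round(plant_rel_pos * template_len)) +
                       1L),
                 template_len - hp_len + 1L)
    n_plant <- as.integer(round(plant_fraction * n_copies))
    carriers <- sort(sample.int(n_copies, n_plant))
    ids <- sprintf("copy%03d", seq_len(n_copies))
    seqs <- character(n_copies)
    truth <- vector("list", n_plant)
    tchars <- strsplit(template, "")[[1]]
    ti <- 0L
    for (k in seq_len(n_copies)) {
      chars <- tchars
      if (k %in% carriers) {
        tail_chars <- if (start + hp_len <= template_len)
          chars[(start + hp_len):template_len] else character(0)
        chars <- c(chars[seq_len(start - 1L)],
                   strsplit(hp$sequence, "")[[1]],
                   tail_chars)
        # keep the flanks from extending the planted stem
        if (start > 1L && start + hp_len <= template_len &&
            COMP[toupper(chars[start - 1L])] ==
              toupper(chars[start + hp_len]))
          chars[start - 1L] <- base_avoiding_pairing(
            chars[start + hp_len])
      }
      # substitution draws are made unconditionally so that the RNG stream
      # does not depend on sub_rate: at a fixed seed, the mutated positions
      # are nested across increasing rates
      u <- runif(length(chars))
      shift <- sample.int(3L, length(chars), replace = TRUE)
      mut <- which(u < sub_rate)
      if (length(mut))
        chars[mut] <- vapply(mut, function(i) {
          alt <- BASES[BASES != toupper(chars[i])]
          alt[(shift[i] - 1L) %% length(alt) + 1L]
        }, character(1))
      seqs[k] <- paste(chars, collapse = "")
      if (k %in% carriers) {
        ti <- ti + 1L
        tr <- hp$truth
        for (col in c("left_start", "left_end", "loop_start", "loop_end",
                      "right_start", "right_end"))
          tr[[col]] <- tr[[col]] + start - 1L
        tr$seq_id <- ids[k]
        bp <- as.integer(strsplit(tr$bulge_positions, ",")[[1]])
        tr$bulge_positions <- paste(bp + start - 1L, collapse = ",")
        truth[[ti]] <- tr
      }
    }
    list(records = data.frame(id = ids, sequence = seqs,
                              stringsAsFactors = FALSE),
         truth = if (n_plant) do.call(rbind, truth) else
           make_hairpin(spec, seed = seed + 1L)$truth[0, ],
         template = template)
  })
}
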