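#' Penalty scheme for arm alignment
#'
#' The stem-search alignment minimises a penalty rather than maximising a
#' score: complementary bases add `match` (0 by default), non-complementary
#' bases add `mismatch`, and gaps add `gap`. All penalties must be
#' non-negative and matches must be strictly cheaper than mismatches and
#' gaps, so that a perfect stem always has penalty 0 under the defaults.
#'
#' @param match Penalty added for a complementary (paired) rung. Default 0.
#' @param mismatch Penalty added for a non-complementary rung. Default 1.
#' @param gap Penalty added for a gap (a bulged base) in either arm.
#'   Default 1.
#' @return An object of class `penalty_scheme`.
#' @examples
#' penalty_scheme()
#' @export
penalty_scheme <- function(match = 0L, mismatch = 1L, gap = 1L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap <- as.integer(gap)
  if (anyNA(c(match, mismatch, gap)) || any(c(match, mismatch, gap) < 0L))
    stop("penalties must be non-negative integers")
  if (match >= mismatch || match >= gap)
    stop("match penalty must be strictly smaller than mismatch and gap penalties")
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "penalty_scheme")
}

#' @export
print.penalty_scheme <- function(x, ...) {
  cat("Penalty scheme: match =", x$match, ", mismatch =", x$mismatch,
      ", gap =", x$gap, "\n")
  invisible(x)
}

#' Stem-loop search parameters
#'
#' Bundles the four search constraints of the stem-loop scan together with
#' the alignment penalty scheme. The defaults are the parameter set used for
#' transposon annotation: stems of 15-50 bp, loops up to 10 bp, and at most
#' 7 mismatches plus gaps in a stem.
#'
#' `min_loop` is an implementation parameter: hairpin loops shorter than
#' about 3 bases are sterically impossible, so candidate loops below
#' `min_loop` are never proposed. Set it to 0 to enumerate every separation
#' down to abutting arms.
#'
#' @param min_stem Minimum stem length (bp) for an accepted hit.
#' @param max_stem Maximum arm window length (bp) considered on each side of
#'   a candidate loop.
#' @param max_loop Maximum loop length (bp), inclusive.
#' @param min_loop Minimum loop length (bp), inclusive. Default 3.
#' @param max_mismatch Maximum total alignment penalty (mismatches plus
#'   gaps, under the default scheme) for an accepted hit.
#' @param penalties A [penalty_scheme()].
#' @return An object of class `stemloop_params`.
#' @examples
#' stemloop_params()
#' stemloop_params(min_stem = 8, max_stem = 10, max_loop = 7, max_mismatch = 2)
#' @export
stemloop_params <- function(min_stem = 15L, max_stem = 50L, max_loop = 10L,
                            min_loop = 3L, max_mismatch = 7L,
                            penalties = penalty_scheme()) {
  min_stem <- as.integer(min_stem); max_stem <- as.integer(max_stem)
  max_loop <- as.integer(max_loop); min_loop <- as.integer(min_loop)
  max_mismatch <- as.integer(max_mismatch)
  if (anyNA(c(min_stem, max_stem, max_loop, min_loop, max_mismatch)))
    stop("search parameters must be integers")
  if (min_stem < 1L || min_stem > max_stem)
    stop("need 1 <= min_stem <= max_stem")
  if (min_loop < 0L || min_loop > max_loop)
    stop("need 0 <= min_loop <= max_loop")
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0")
  if (!inherits(penalties, "penalty_scheme"))
    stop("'penalties' must be a penalty_scheme object")
  structure(list(min_stem = min_stem, max_stem = max_stem,
                 max_loop = max_loop, min_loop = min_loop,
                 max_mismatch = max_mismatch, penalties = penalties),
            class = "stemloop_params")
}

#' @export
print.stemloop_params <- function(x, ...) {
  cat("Stem-loop search parameters\n")
  cat("  stem length : ", x$min_stem, "-", x$max_stem, " bp\n", sep = "")
  cat("  loop length : ", x$min_loop, "-", x$max_loop, " bp\n", sep = "")
  cat("  max penalty : ", x$max_mismatch,
      " (mismatches + gaps)\n", sep = "")
  print(x$penalties)
  invisible(x)
}
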