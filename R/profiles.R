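#' Stem-loop coverage profile of a sequence family
#'
#' For every sequence, the covered set is the union of hit footprints (both
#' arms and the loop). Sequences are scaled to a common normalised length:
#' base \eqn{i} (1-based) of a sequence of length \eqn{L} maps to bin
#' \eqn{\lfloor (i-1) \cdot n/L \rfloor + 1} of \eqn{n} bins, and a bin
#' counts as covered for a sequence when at least one of its bases is
#' covered. The profile value at a bin is the fraction of sequences covered
#' there, so the y-axis reads as a percentage of sequences once multiplied
#' by 100.
#'
#' @param hits A `stemloop_hits` data frame (e.g. from [scan_stemloops()]).
#'   May reference only sequences present in `seq_lengths`.
#' @param seq_lengths Named integer vector of sequence lengths, one per
#'   family member; members without hits must still be listed, since they
#'   contribute to the denominator.
#' @param n_bins Number of normalised-length bins (default 100, i.e.
#'   percent of sequence length). Use `n_bins = NULL` for per-base
#'   resolution, which requires all sequences to have equal length.
#' @return A data frame of class `coverage_profile` with columns `bin` and
#'   `value` (fraction in \[0, 1\]), and attributes `n_sequences` and
#'   `n_bins`.
#' @examples
#' seqs <- c(s1 = paste0(strrep("A", 50), "GGGCAAAAGCCC", strrep("A", 38)),
#'           s2 = strrep("A", 100))
#' hits <- scan_stemloops(seqs, stemloop_params(min_stem = 3, max_stem = 6,
#'                                              max_loop = 5, max_mismatch = 0))
#' cp <- coverage_profile(hits, c(s1 = 100, s2 = 100))
#' cp$value[51:62]  # 0.5 across the hit footprint: one of two sequences
#' @export
coverage_profile <- function(hits, seq_lengths, n_bins = 100L) {
  if (length(seq_lengths) == 0L)
    stop("empty family: 'seq_lengths' must name at least one sequence")
  if (is.null(names(seq_lengths)) || any(!nzchar(names(seq_lengths))))
    stop("'seq_lengths' must be a named vector of sequence lengths")
  stopifnot(is.data.frame(hits))
  unknown <- setdiff(unique(hits$seq_id), names(seq_lengths))
  if (length(unknown))
    stop("hits reference sequences absent from 'seq_lengths': ",
         paste(unknown, collapse = ", "))
  per_bp <- is.null(n_bins)
  if (per_bp) {
    if (length(unique(seq_lengths)) != 1L)
      stop("per-base profiles (n_bins = NULL) require equal-length sequences")
    n_bins <- unname(seq_lengths[1])
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("'n_bins' must be >= 1")
  counts <- integer(n_bins)
  for (id in names(seq_lengths)) {
    L <- as.integer(seq_lengths[[id]])
    h <- hits[hits$seq_id == id, , drop = FALSE]
    if (!nrow(h)) next
    if (any(h$left_start < 1L) || any(h$right_end > L))
      stop("hit outside sequence bounds for ", id)
    covered <- logical(L)
    for (k in seq_len(nrow(h)))
      covered[h$left_start[k]:h$right_end[k]] <- TRUE
    bins <- unique(floor((which(covered) - 1L) * n_bins / L) + 1L)
    counts[bins] <- counts[bins] + 1L
  }
  structure(data.frame(bin = seq_len(n_bins),
                       value = counts / length(seq_lengths)),
            n_sequences = length(seq_lengths), n_bins = n_bins,
            per_bp = per_bp,
            class = c("coverage_profile", "data.frame"))
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("Stem-loop coverage profile: ", attr(x, "n_bins"), " bins over ",
      attr(x, "n_sequences"), " sequence(s); peak ",
      round(max(x$value), 3), " at bin ", which.max(x$value), "\n", sep = "")
  invisible(x)
}

#' @param x A `coverage_profile`.
#' @param ... Passed to [graphics::plot()].
#' @rdname coverage_profile
#' @export
plot.coverage_profile <- function(x, ...) {
  graphics::plot(x$bin, 100 * x$value, type = "h",
                 xlab = if (isTRUE(attr(x, "per_bp"))) "position (bp)"
                        else "normalised position (bin)",
                 ylab = "% of sequences covered", ...)
  invisible(x)
}

#' Pairing-unpairing profile of a set of hairpin structures
#'
#' Localises bulges and internal loops across a collection of single-hairpin
#' secondary structures. Each structure contributes 1 wherever it has an
#' unpaired base, and the profile reports, per coordinate, how many
#' structures are unpaired there. Two coordinate systems are available:
#'
#' * `"from_loop"`: stem-anchored. Walking each arm from the loop-closing
#'   rung (x = 0) towards the stem base, a structure contributes 1 at
#'   offset x when unpaired bases interrupt the arm between rung x-1 and
#'   rung x. With `arms = "combined"` an interruption of either arm counts
#'   once; with `arms = "per_arm"` the 5' and 3' arms are reported
#'   separately.
#' * `"normalized_100"`: the whole structure is scaled to 100 bins and a
#'   structure contributes 1 at every bin containing at least one of its
#'   unpaired bases (loop included).
#'
#' @param structures A list of [secondary_structure()] objects, each with
#'   at least one pair and exactly one hairpin loop.
#' @param mode `"from_loop"` (default) or `"normalized_100"`.
#' @param arms `"combined"` (default) or `"per_arm"`; only used in
#'   `"from_loop"` mode.
#' @return A data frame of class `pairing_profile`: columns `offset` and
#'   `count` (or `left`/`right` counts when `arms = "per_arm"`) in
#'   `"from_loop"` mode; columns `bin` and `count` in `"normalized_100"`
#'   mode. Attributes record `mode`, `arms` and `n_structures`.
#' @examples
#' s <- parse_dot_bracket("GGGGGGAAAACCCTCCC", "((((((....))).)))")
#' pairing_profile(list(s))  # one 3'-arm interruption, 3 rungs from the loop
#' @export
pairing_profile <- function(structures,
                            mode = c("from_loop", "normalized_100"),
                            arms = c("combined", "per_arm")) {
  mode <- match.arg(mode); arms <- match.arg(arms)
  if (inherits(structures, "secondary_structure"))
    structures <- list(structures)
  if (!length(structures)) stop("no structures supplied")
  for (s in structures) {
    if (!inherits(s, "secondary_structure"))
      stop("'structures' must be a list of secondary_structure objects")
    if (nrow(s$pairs) == 0L)
      stop("structures with zero pairs are rejected")
    if (count_hairpin_loops(s) != 1L)
      stop("unsupported structure: pairing profiles require exactly one ",
           "hairpin loop per structure")
  }
  n <- length(structures)
  if (mode == "normalized_100") {
    counts <- integer(100)
    for (s in structures) {
      L <- nchar(s$sequence)
      unpaired <- setdiff(seq_len(L), as.vector(s$pairs))
      bins <- unique(floor((unpaired - 1L) * 100L / L) + 1L)
      counts[bins] <- counts[bins] + 1L
    }
    return(structure(data.frame(bin = 1:100, count = counts),
                     mode = mode, arms = arms, n_structures = n,
                     class = c("pairing_profile", "data.frame")))
  }
  # from_loop: order rungs loop-outward; the k-th outward step may be
  # interrupted on either arm
  per_struct <- lapply(structures, function(s) {
    p <- s$pairs[order(-s$pairs[, 1]), , drop = FALSE]  # innermost first
    nr <- nrow(p)
    left <- logical(nr); right <- logical(nr)  # offset x = 1 .. nr-1 used
    if (nr > 1L) for (k in 2:nr) {
      left[k] <- (p[k - 1L, 1] - p[k, 1]) > 1L
      right[k] <- (p[k, 2] - p[k - 1L, 2]) > 1L
    }
    list(left = left, right = right)
  })
  max_x <- max(vapply(per_struct, function(z) length(z$left), integer(1)))
  pad <- function(v) c(v, logical(max_x - length(v)))
  collect <- function(f) {
    m <- matrix(vapply(per_struct, f, logical(max_x)), nrow = max_x)
    as.integer(rowSums(m))
  }
  left <- collect(function(z) pad(z$left))
  right <- collect(function(z) pad(z$right))
  both <- collect(function(z) pad(z$left) | pad(z$right))
  df <- if (arms == "per_arm")
    data.frame(offset = 0:(max_x - 1L), left = left, right = right)
  else
    data.frame(offset = 0:(max_x - 1L), count = both)
  structure(df, mode = mode, arms = arms, n_structures = n,
            class = c("pairing_profile", "data.frame"))
}

#' @export
print.pairing_profile <- function(x, ...) {
  cat("Pairing-unpairing profile (", attr(x, "mode"), ", ",
      attr(x, "arms"), ") over ", attr(x, "n_structures"),
      " structure(s)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' @param x A `pairing_profile`.
#' @param ... Passed to [graphics::plot()].
#' @rdname pairing_profile
#' @export
plot.pairing_profile <- function(x, ...) {
  xv <- if ("offset" %in% names(x)) x$offset else x$bin
  yv <- if ("count" %in% names(x)) x$count else x$left + x$right
  graphics::plot(xv, yv, type = "h",
                 xlab = if ("offset" %in% names(x))
                   "stem rungs from the loop" else "normalised position",
                 ylab = "structures with unpaired base", ...)
  invisible(x)
}
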