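#' Test Watson-Crick complementarity of two DNA bases
#'
#' A stem rung is a "match" when the two bases are complementary (A with T,
#' C with G). Comparison is case-insensitive; `N` never pairs with anything,
#' and G-T wobble pairs are not allowed at the DNA level.
#'
#' @param a,b Single characters in `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive). Vectors are recycled elementwise.
#' @return Logical vector.
#' @examples
#' is_complementary("T", "A")  # TRUE
#' is_complementary("G", "T")  # FALSE: no wobble in the DNA search
#' @export
is_complementary <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  ok <- c("A", "C", "G", "T", "N")
  if (!all(a %in% ok) || !all(b %in% ok))
    stop("invalid alphabet: bases must be one of A, C, G, T, N")
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Fill the minimum-penalty arm-alignment matrix
#'
#' Aligns two candidate stem arms, both given with their loop-proximal end
#' first, under a penalty-minimising variant of Needleman-Wunsch: matches
#' (complementary bases) are free by default, mismatches and gaps cost 1.
#' Cell \eqn{(i,j)} of the returned matrix holds the minimum penalty of any
#' gapped alignment of the first \eqn{i-1} bases of `arm_a` against the
#' first \eqn{j-1} bases of `arm_b`; the header row and column hold the
#' cumulative gap penalties (the substring coordinates 0, 1, 2, ... under
#' the default gap cost of 1).
#'
#' @param arm_a,arm_b DNA strings, loop-proximal end first. `arm_a` is
#'   conventionally the left (5') arm read right-to-left, `arm_b` the right
#'   (3') arm read left-to-right.
#' @param penalties A [penalty_scheme()].
#' @return An integer matrix of class `stemloop_dp` of size
#'   `(nchar(arm_a)+1) x (nchar(arm_b)+1)`, with the arms stored in
#'   attributes `arm_a`, `arm_b` and the scheme in `penalties`.
#' @examples
#' m <- dp_fill("TACG", "AATGC")
#' m[2, 2]  # 0: min(M[1,1] + 0, M[1,2] + 1, M[2,1] + 1)
#' @export
dp_fill <- function(arm_a, arm_b, penalties = penalty_scheme()) {
  check_dna(arm_a, "arm_a"); check_dna(arm_b, "arm_b")
  if (nchar(arm_a) == 0L || nchar(arm_b) == 0L)
    stop("arms must be non-empty")
  if (!inherits(penalties, "penalty_scheme"))
    stop("'penalties' must be a penalty_scheme object")
  m <- .dp_fill_cpp(toupper(arm_a), toupper(arm_b),
                    penalties$match, penalties$mismatch, penalties$gap)
  dimnames(m) <- list(c("-", strsplit(toupper(arm_a), "")[[1]]),
                      c("-", strsplit(toupper(arm_b), "")[[1]]))
  structure(m, arm_a = arm_a, arm_b = arm_b, penalties = penalties,
            class = c("stemloop_dp", "matrix", "array"))
}

#' @export
print.stemloop_dp <- function(x, ...) {
  cat("Minimum-penalty arm alignment matrix (",
      nrow(x) - 1L, " x ", ncol(x) - 1L, " arms)\n", sep = "")
  print(unclass(structure(x, arm_a = NULL, arm_b = NULL, penalties = NULL)))
  invisible(x)
}

#' Select the traceback start cell of a filled arm matrix
#'
#' Scans the interior of a filled alignment matrix for the cell that
#' maximises the minimum of its coordinates (the guaranteed aligned stem
#' length) among cells whose penalty does not exceed `max_mismatch` and
#' whose minimum coordinate corresponds to at least `min_stem` aligned
#' bases. Ties are resolved by lowest penalty, then lowest maximum
#' coordinate (shortest overhang), then a strand-symmetric comparison of
#' the two arm prefixes, and finally lowest row.
#'
#' @param m A matrix from [dp_fill()].
#' @param params A [stemloop_params()] (only `max_mismatch` and `min_stem`
#'   are used).
#' @return Integer vector `c(i, j)` of 1-based matrix coordinates, or
#'   `NULL` when no cell qualifies (no acceptable stem).
#' @examples
#' m <- dp_fill("CGGG", "GCCC")
#' select_start_cell(m, stemloop_params(min_stem = 2, max_stem = 4,
#'                                      max_loop = 5, max_mismatch = 0))
#' @export
select_start_cell <- function(m, params = stemloop_params()) {
  stopifnot(inherits(m, "stemloop_dp"), inherits(params, "stemloop_params"))
  ij <- .select_start_cpp(unclass(m)[, , drop = FALSE],
                          toupper(attr(m, "arm_a")),
                          toupper(attr(m, "arm_b")),
                          params$max_mismatch, params$min_stem)
  if (ij[1] == 0L) NULL else ij
}

#' Trace back an arm alignment from a start cell
#'
#' Recovers the alignment path from `start` back to the matrix origin,
#' always stepping to a predecessor consistent with the fill recurrence and
#' of minimal value (diagonal preferred on ties). The alignment is rejected
#' (returns `NULL`) unless its loop-closing rung -- the first aligned
#' position -- is a complementary pair, so that stems never begin with a
#' mismatch or gap.
#'
#' @param m A matrix from [dp_fill()].
#' @param start Integer vector `c(i, j)` as returned by
#'   [select_start_cell()].
#' @return An object of class `arm_alignment` with elements `events` (a
#'   string over `P` pair / `M` mismatch / `A` gap in arm A / `B` gap in
#'   arm B, ordered from the loop outward), `penalty`, `len_a`, `len_b`
#'   (consumed arm lengths) and `stem_len` (their minimum); or `NULL` when
#'   the loop-closing rung is not a pair.
#' @examples
#' m <- dp_fill("CGGG", "GCCC")
#' trace_arm_alignment(m, c(5, 5))
#' @export
trace_arm_alignment <- function(m, start) {
  stopifnot(inherits(m, "stemloop_dp"), length(start) == 2L)
  res <- .traceback_cpp(unclass(m)[, , drop = FALSE],
                        toupper(attr(m, "arm_a")),
                        toupper(attr(m, "arm_b")),
                        as.integer(start[1]), as.integer(start[2]),
                        attr(m, "penalties")$match,
                        attr(m, "penalties")$mismatch,
                        attr(m, "penalties")$gap)
  if (is.null(res)) return(NULL)
  structure(list(events = res$events, penalty = res$penalty,
                 len_a = res$len_a, len_b = res$len_b,
                 stem_len = min(res$len_a, res$len_b)),
            class = "arm_alignment")
}

#' @export
print.arm_alignment <- function(x, ...) {
  cat("Arm alignment: penalty ", x$penalty, ", consumed ",
      x$len_a, "/", x$len_b, " bases, events ", x$events, "\n", sep = "")
  invisible(x)
}

# Decompose an event string into per-event consumed indices (1 = loop-
# proximal base) of each arm; used by hit_to_structure and reporting.
alignment_event_table <- function(events) {
  ev <- strsplit(events, "")[[1]]
  a <- integer(length(ev)); b <- integer(length(ev))
  ia <- 0L; ib <- 0L
  for (k in seq_along(ev)) {
    if (ev[k] %in% c("P", "M")) {
      ia <- ia + 1L; ib <- ib + 1L; a[k] <- ia; b[k] <- ib
    } else if (ev[k] == "B") {        # gap in arm B consumes arm A
      ia <- ia + 1L; a[k] <- ia; b[k] <- NA_integer_
    } else {                          # gap in arm A consumes arm B
      ib <- ib + 1L; a[k] <- NA_integer_; b[k] <- ib
    }
  }
  data.frame(event = ev, a = a, b = b, stringsAsFactors = FALSE)
}
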