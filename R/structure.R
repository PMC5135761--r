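#' Construct a secondary structure object
#'
#' A base-pairing assignment over a sequence: a set of nested
#' (non-crossing) index pairs, each base in at most one pair. This is the
#' representation behind dot-bracket notation and the input to
#' [pairing_profile()].
#'
#' @param sequence The nucleotide string.
#' @param pairs A two-column integer matrix of 1-based paired positions
#'   (column 1 < column 2), possibly with zero rows.
#' @param source One of `"imported_dot_bracket"`, `"from_hit_alignment"`,
#'   `"fallback_fold"`.
#' @param id Optional identifier.
#' @return An object of class `secondary_structure`.
#' @export
secondary_structure <- function(sequence, pairs,
                                source = c("imported_dot_bracket",
                                           "from_hit_alignment",
                                           "fallback_fold"),
                                id = NULL) {
  source <- match.arg(source)
  check_dna(sequence)
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  n <- nchar(sequence)
  if (nrow(pairs)) {
    if (any(pairs < 1L) || any(pairs > n))
      stop("pair indices out of range")
    if (any(pairs[, 1] >= pairs[, 2]))
      stop("pairs must satisfy i < j")
    idx <- as.vector(pairs)
    if (anyDuplicated(idx))
      stop("a base may participate in at most one pair")
    # non-crossing check: for sorted pairs, any pair opening inside another
    # must also close inside it
    o <- order(pairs[, 1])
    p <- pairs[o, , drop = FALSE]
    if (nrow(p) > 1L) {
      for (k in seq_len(nrow(p) - 1L)) {
        inside <- p[-seq_len(k), 1] < p[k, 2]
        if (any(p[-seq_len(k), 2][inside] > p[k, 2]))
          stop("pairs are crossing (pseudoknots are not supported)")
      }
    }
  }
  structure(list(sequence = sequence, pairs = pairs, source = source,
                 id = id),
            class = "secondary_structure")
}

#' Parse Vienna dot-bracket notation
#'
#' @param seq The nucleotide string.
#' @param db The dot-bracket string: `(` and `)` for paired bases, `.` for
#'   unpaired; must have the same length as `seq` and balanced brackets.
#' @param id Optional identifier.
#' @return A [secondary_structure()].
#' @examples
#' parse_dot_bracket("GGAATT", "((..))")
#' @export
parse_dot_bracket <- function(seq, db, id = NULL) {
  if (nchar(seq) != nchar(db))
    stop("sequence and structure strings differ in length")
  ch <- strsplit(db, "")[[1]]
  bad <- setdiff(unique(ch), c("(", ")", "."))
  if (length(bad))
    stop("invalid dot-bracket character(s): ",
         paste(sQuote(bad), collapse = ", "))
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  out <- vector("list", sum(ch == ")"))
  np <- 0L
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      if (!length(stack))
        stop("unbalanced dot-bracket string: unmatched ')' at position ", k)
      np <- np + 1L
      out[[np]] <- c(stack[length(stack)], k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop("unbalanced dot-bracket string: unmatched '(' at position ",
         stack[1])
  if (np) pairs <- do.call(rbind, out[seq_len(np)])
  secondary_structure(seq, pairs, source = "imported_dot_bracket", id = id)
}

#' Write a structure as a dot-bracket string
#'
#' Inverse of [parse_dot_bracket()] on valid (nested) structures.
#'
#' @param x A [secondary_structure()].
#' @return A single dot-bracket string.
#' @examples
#' as_dot_bracket(parse_dot_bracket("GGAATT", "((..))"))
#' @export
as_dot_bracket <- function(x) {
  stopifnot(inherits(x, "secondary_structure"))
  ch <- rep(".", nchar(x$sequence))
  if (nrow(x$pairs)) {
    ch[x$pairs[, 1]] <- "("
    ch[x$pairs[, 2]] <- ")"
  }
  paste(ch, collapse = "")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("Secondary structure (", x$source, ", ", nrow(x$pairs),
      " pairs)\n", sep = "")
  if (!is.null(x$id)) cat(">", x$id, "\n", sep = "")
  cat(x$sequence, "\n", as_dot_bracket(x), "\n", sep = "")
  invisible(x)
}

#' Convert a stem-loop hit to a secondary structure
#'
#' Each complementary-pair event of the hit's arm alignment becomes a base
#' pair; mismatch and gap events leave the corresponding bases unpaired, as
#' do all loop bases and any sequence outside the hit footprint.
#'
#' @param hit A one-row `stemloop_hits` data frame (or a row index into a
#'   larger one via `hit[k, ]`).
#' @param seq The DNA sequence the hit was found on.
#' @return A [secondary_structure()] with source `"from_hit_alignment"`.
#' @examples
#' p <- stemloop_params(min_stem = 3, max_stem = 6, max_loop = 5,
#'                      max_mismatch = 0)
#' h <- scan_stemloops("GGGCAAAAGCCC", p)
#' as_dot_bracket(hit_to_structure(h[1, ], "GGGCAAAAGCCC"))
#' @export
hit_to_structure <- function(hit, seq) {
  stopifnot(is.data.frame(hit), nrow(hit) == 1L)
  check_dna(seq)
  if (hit$right_end > nchar(seq) || hit$left_start < 1L)
    stop("hit coordinates out of bounds for the given sequence")
  ev <- alignment_event_table(hit$events)
  pe <- ev[ev$event == "P", , drop = FALSE]
  # arm offsets count from the loop: left arm base k sits at left_end-k+1,
  # right arm base k at right_start+k-1
  pairs <- cbind(hit$left_end - pe$a + 1L, hit$right_start + pe$b - 1L)
  secondary_structure(seq, pairs, source = "from_hit_alignment",
                      id = hit$seq_id)
}

#' Deterministic base-pair-maximisation fold
#'
#' A nested-structure fold that maximises the number of admissible base
#' pairs subject to hairpin loops of at least `min_loop` unpaired bases
#' (the classic interval dynamic programme). It is a deterministic,
#' thermodynamics-free fallback for when no external fold output is
#' available; ties are broken by pairing the leftmost base first with its
#' nearest admissible partner.
#'
#' @param seq Nucleotide string (DNA or RNA).
#' @param min_loop Minimum hairpin loop length in bases. Default 3.
#' @param rna When `TRUE`, G-U (G-T) wobble pairs are admissible in
#'   addition to Watson-Crick pairs. Default `FALSE` (DNA mode).
#' @param id Optional identifier.
#' @return A [secondary_structure()] with source `"fallback_fold"`.
#' @examples
#' as_dot_bracket(fold_max_pairs("GGGAAACCC"))  # "(((...)))"
#' @export
fold_max_pairs <- function(seq, min_loop = 3L, rna = FALSE, id = NULL) {
  check_dna(seq)
  if (nchar(seq) < 1L) stop("sequence must be non-empty")
  pt <- .fold_cpp(toupper(seq), as.integer(min_loop), isTRUE(rna))
  i <- which(pt > seq_along(pt))
  pairs <- cbind(i, pt[i])
  secondary_structure(seq, pairs, source = "fallback_fold", id = id)
}

# Number of hairpin loops = number of pairs with no pair nested inside.
count_hairpin_loops <- function(x) {
  p <- x$pairs
  if (!nrow(p)) return(0L)
  inner <- vapply(seq_len(nrow(p)), function(k) {
    !any(p[, 1] > p[k, 1] & p[, 2] < p[k, 2])
  }, logical(1))
  sum(inner)
}
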