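#' Search for a stem-loop closing a given loop span
#'
#' Builds the two candidate arm windows flanking the loop span (up to
#' `max_stem` bases on each side, the left window reversed so both arms read
#' from the loop outward), fills the minimum-penalty alignment matrix,
#' selects the start cell and traces the alignment back. Coordinates are
#' 1-based and inclusive.
#'
#' @param seq A DNA string.
#' @param loop_start,loop_end 1-based inclusive span of the candidate loop;
#'   its length must lie within `params$min_loop .. params$max_loop`.
#' @param params A [stemloop_params()].
#' @param seq_id Sequence identifier recorded in the hit.
#' @return A one-row `stemloop_hits` data frame, or `NULL` when no
#'   qualifying stem exists.
#' @examples
#' find_stem_loop_at("GGGCAAAAGCCC", 5, 8,
#'   stemloop_params(min_stem = 3, max_stem = 6, max_loop = 5,
#'                   max_mismatch = 0))
#' @export
find_stem_loop_at <- function(seq, loop_start, loop_end,
                              params = stemloop_params(), seq_id = "seq") {
  check_dna(seq)
  L <- nchar(seq)
  loop_start <- as.integer(loop_start); loop_end <- as.integer(loop_end)
  if (loop_start < 1L || loop_end > L || loop_end < loop_start - 1L)
    stop("loop span [", loop_start, ", ", loop_end,
         "] out of bounds for a sequence of length ", L)
  llen <- loop_end - loop_start + 1L
  if (llen < params$min_loop || llen > params$max_loop)
    stop("loop length ", llen, " outside [min_loop, max_loop]")
  a <- loop_start - 1L          # bases available to the left
  kb <- min(L - loop_end, params$max_stem)
  ka <- min(a, params$max_stem)
  if (ka < params$min_stem || kb < params$min_stem) return(NULL)
  s <- toupper(seq)
  arm_a <- paste(rev(strsplit(substr(s, a - ka + 1L, a), "")[[1]]),
                 collapse = "")
  arm_b <- substr(s, loop_end + 1L, loop_end + kb)
  m <- dp_fill(arm_a, arm_b, params$penalties)
  ij <- select_start_cell(m, params)
  if (is.null(ij)) return(NULL)
  aln <- trace_arm_alignment(m, ij)
  if (is.null(aln)) return(NULL)
  new_hits(data.frame(
    seq_id = seq_id,
    left_start = a - aln$len_a + 1L, left_end = a,
    loop_start = loop_start, loop_end = loop_end,
    right_start = loop_end + 1L, right_end = loop_end + aln$len_b,
    stem_len = aln$stem_len, loop_len = llen, penalty = aln$penalty,
    events = aln$events, stringsAsFactors = FALSE))
}

new_hits <- function(df) {
  class(df) <- c("stemloop_hits", "data.frame")
  df
}

empty_hits <- function() {
  new_hits(data.frame(
    seq_id = character(), left_start = integer(), left_end = integer(),
    loop_start = integer(), loop_end = integer(), right_start = integer(),
    right_end = integer(), stem_len = integer(), loop_len = integer(),
    penalty = integer(), events = character(), stringsAsFactors = FALSE))
}

#' Scan sequences for stem-loop structures
#'
#' Enumerates every candidate loop span of length `min_loop` to `max_loop`
#' along each sequence, searches for a qualifying stem closing it (see
#' [find_stem_loop_at()]), removes redundant hits and returns the remainder
#' sorted by position. Two hits are redundant when their loop-closing rungs
#' occupy the same sequence positions; the one with the longer stem, then
#' the lower penalty, is kept. Overlapping non-redundant hits are all
#' retained: the coverage profile uses the union of covered bases.
#'
#' @param x Sequences: a (optionally named) character vector, or a data
#'   frame with columns `id` and `sequence` as returned by [read_fasta()].
#' @param params A [stemloop_params()].
#' @return A `stemloop_hits` data frame with 1-based inclusive columns
#'   `left_start`/`left_end` (5' arm), `loop_start`/`loop_end`,
#'   `right_start`/`right_end` (3' arm), plus `stem_len`, `loop_len`,
#'   `penalty` and the loop-outward alignment event string `events`
#'   (`P` pair, `M` mismatch, `A`/`B` gap in the right/left arm window).
#'   Sequences shorter than `2 * min_stem + min_loop` yield no rows.
#' @examples
#' scan_stemloops("GGGCAAAAGCCC",
#'   stemloop_params(min_stem = 3, max_stem = 6, max_loop = 5,
#'                   max_mismatch = 0))
#' @export
scan_stemloops <- function(x, params = stemloop_params()) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    seqs <- as.character(x$sequence); ids <- as.character(x$id)
  } else {
    seqs <- as.character(x)
    ids <- if (!is.null(names(x))) names(x) else
      if (length(seqs) == 1L) "seq" else paste0("seq", seq_along(seqs))
  }
  stopifnot(inherits(params, "stemloop_params"))
  out <- lapply(seq_along(seqs), function(k) {
    check_dna(seqs[k], paste0("sequence '", ids[k], "'"))
    if (nchar(seqs[k]) < 2L * params$min_stem + params$min_loop)
      return(empty_hits())
    h <- .scan_cpp(toupper(seqs[k]), params$min_stem, params$max_stem,
                   params$min_loop, params$max_loop, params$max_mismatch,
                   params$penalties$match, params$penalties$mismatch,
                   params$penalties$gap)
    if (nrow(h) == 0L) return(empty_hits())
    h$seq_id <- ids[k]
    h$loop_len <- h$loop_end - h$loop_start + 1L
    h <- dedup_hits(h)
    h <- h[order(h$left_start, h$right_end, h$loop_start), ]
    rownames(h) <- NULL
    new_hits(h[, names(empty_hits())])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  new_hits(res)
}

# Redundancy rule: same loop-closing rung (positions left_end and
# right_start); keep longest stem, then lowest penalty.
dedup_hits <- function(h) {
  key <- paste(h$left_end, h$right_start)
  ord <- order(key, -h$stem_len, h$penalty)
  h <- h[ord, ]
  h[!duplicated(paste(h$left_end, h$right_start)), ]
}

#' @export
print.stemloop_hits <- function(x, ...) {
  cat("Stem-loop hits:", nrow(x), "hit(s) on",
      length(unique(x$seq_id)), "sequence(s)\n")
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}
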