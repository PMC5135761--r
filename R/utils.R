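# internal helpers shared across modules

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("'", what, "' must be a single character string")
  bad <- setdiff(unique(strsplit(toupper(seq), "")[[1]]), IUPAC_CHARS)
  if (length(bad))
    stop("invalid character(s) in ", what, ": ",
         paste(sQuote(bad), collapse = ", "))
  invisible(seq)
}

#' Reverse complement of a DNA sequence
#'
#' @param seq A single DNA string (IUPAC codes allowed; case preserved).
#' @return The reverse complement as a character string.
#' @examples
#' reverse_complement("GGGCAAAAGCCC")
#' @export
reverse_complement <- function(seq) {
  check_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
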