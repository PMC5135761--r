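#' Read a (multi-)FASTA file of DNA sequences
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` (first whitespace-delimited token
#'   of each header) and `sequence`. Lower-case bases are preserved;
#'   scanning is case-insensitive.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA file '",
                                           path, "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1)
  if (any(!nzchar(ids))) stop("FASTA record with empty identifier in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA identifier(s): ", paste(dup, collapse = ", "))
  seqs <- as.character(set)
  for (k in seq_along(seqs)) {
    seqs[k] <- gsub("[ \t\r]", "", seqs[k])
    if (!nzchar(seqs[k])) stop("empty sequence for record ", ids[k])
    check_dna(seqs[k], paste0("record '", ids[k], "'"))
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param x A data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width. Default 70.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(is.data.frame(x), all(c("id", "sequence") %in% names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[k]), con)
    s <- x$sequence[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Write stem-loop hits as BED6 (and optionally a detailed TSV)
#'
#' The BED interval spans the whole hit footprint (left arm through right
#' arm) in 0-based half-open convention: `chromStart = left_start - 1`,
#' `chromEnd = right_end`. The name field is `"stemloop"`, the score is the
#' alignment penalty and the strand `"+"`. The optional TSV carries the
#' full 1-based sub-coordinates (arms, loop) plus the alignment event
#' string.
#'
#' @param hits A `stemloop_hits` data frame.
#' @param path Output BED path.
#' @param tsv_path Optional path for the detailed TSV.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, tsv_path = NULL) {
  stopifnot(is.data.frame(hits))
  bed <- data.frame(chrom = hits$seq_id,
                    chromStart = hits$left_start - 1L,
                    chromEnd = hits$right_end,
                    name = rep("stemloop", nrow(hits)),
                    score = hits$penalty,
                    strand = rep("+", nrow(hits)))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv_path))
    write.table(as.data.frame(hits), tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read stem-loop hit coordinates back from BED6
#'
#' Only the footprint span, penalty and sequence id survive the BED round
#' trip; use the detailed TSV written by [write_hits_bed()] to recover arm
#' and loop sub-coordinates.
#'
#' @param path A BED file written by [write_hits_bed()].
#' @return A data frame with columns `seq_id`, `start`, `end` (1-based
#'   inclusive) and `penalty`.
#' @export
read_hits_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), penalty = integer()))
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "chromStart", "chromEnd",
                                  "name", "score", "strand"),
                    stringsAsFactors = FALSE)
  data.frame(seq_id = bed$chrom, start = bed$chromStart + 1L,
             end = bed$chromEnd, penalty = bed$score,
             stringsAsFactors = FALSE)
}

#' Read the detailed hits TSV written by [write_hits_bed()]
#'
#' @param path TSV path.
#' @return A `stemloop_hits` data frame.
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(events = "character",
                                  seq_id = "character"),
                   stringsAsFactors = FALSE)
  new_hits(df)
}

#' Write a coverage or pairing profile as TSV
#'
#' Column 1 is the bin or stem offset, the remaining column(s) the profile
#' value(s).
#'
#' @param profile A `coverage_profile` or `pairing_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(is.data.frame(profile))
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read secondary structures from a Vienna-style dot-bracket file
#'
#' Records follow the Vienna convention: an optional `>id` header line,
#' then a sequence line, then a structure line of the same length
#' (anything after whitespace on the structure line, such as an energy
#' annotation, is ignored).
#'
#' @param path Input path.
#' @return A list of [secondary_structure()] objects.
#' @export
read_dot_bracket <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  k <- 1L
  while (k <= length(lines)) {
    id <- NULL
    if (startsWith(lines[k], ">")) {
      id <- sub("^>\\s*", "", lines[k])
      k <- k + 1L
    }
    if (k + 1L > length(lines))
      stop("truncated dot-bracket record at line ", k)
    seq <- trimws(lines[k])
    db <- strsplit(trimws(lines[k + 1L]), "\\s+")[[1]][1]
    out[[length(out) + 1L]] <- parse_dot_bracket(seq, db, id = id)
    k <- k + 2L
  }
  if (!length(out)) stop("no dot-bracket records in ", path)
  out
}

#' Write secondary structures to a Vienna-style dot-bracket file
#'
#' @param structures A [secondary_structure()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dot_bracket <- function(structures, path) {
  if (inherits(structures, "secondary_structure"))
    structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    stopifnot(inherits(s, "secondary_structure"))
    writeLines(paste0(">", if (is.null(s$id)) paste0("structure", k)
                           else s$id), con)
    writeLines(s$sequence, con)
    writeLines(as_dot_bracket(s), con)
  }
  invisible(path)
}
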