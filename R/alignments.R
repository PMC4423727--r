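# Paired-read alignment ingestion. Three dialects are accepted: SAM, legacy
# Bowtie tabular (pre-Bowtie2 default output), and BLAST tabular (-outfmt 6).
# All coordinates are normalised to 0-based half-open intervals on the contig
# forward strand; unmapped records are dropped.

#' Parse read alignments
#'
#' @param path alignment file (plain or gzip).
#' @param format one of "sam", "bowtie", "blast".
#' @param contigs contig set (named character vector) used to validate
#'   reference ids and coordinates.
#' @return a data.table with columns read_id, pair_id, mate (1/2 or NA),
#'   contig, start, end (0-based half-open), strand ("+"/"-"), mult (number
#'   of reported placements for that read end).
#' @details Strand decoding per dialect: SAM FLAG bit 0x10; the Bowtie strand
#'   column; BLAST subject-coordinate order (s.start > s.end means minus).
#'   Mate indices come from SAM FLAG bits 0x40/0x80 when the paired bit is
#'   set, otherwise from a trailing `/1`,`/2`,`_1`,`_2` read-id token.
#' @export
read_alignments <- function(path, format = c("sam", "bowtie", "blast"),
                            contigs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    lines <- readLines(con)
  } else {
    lines <- data.table::fread(file = path, sep = "", header = FALSE,
                               quote = "", strip.white = FALSE,
                               colClasses = "character",
                               showProgress = FALSE)
    lines <- if (nrow(lines)) lines[[1]] else character()
  }
  lineno <- seq_along(lines)
  out <- switch(format,
    sam    = parse_sam_lines(lines, lineno),
    bowtie = parse_bowtie_lines(lines, lineno),
    blast  = parse_blast_lines(lines, lineno))
  if (nrow(out)) {
    out[, mult := .N, by = read_id]
    if (!is.null(contigs)) {
      bad <- setdiff(unique(out$contig), names(contigs))
      if (length(bad))
        stop("alignment references unknown contig(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
      clen <- nchar(contigs)[out$contig]
      if (any(out$start < 0L | out$end > clen | out$start >= out$end))
        stop("alignment coordinates outside contig bounds in ", path)
    }
  }
  out[]
}

empty_alignments <- function() {
  data.table::data.table(read_id = character(), pair_id = character(),
                         mate = integer(), contig = character(),
                         start = integer(), end = integer(),
                         strand = character(), mult = integer())
}

# reference span consumed by a CIGAR string (M/D/N/=/X ops)
cigar_ref_span <- function(cigar) {
  span <- rep(NA_integer_, length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  span[simple] <- as.integer(sub("M$", "", cigar[simple]))
  rest <- which(!simple)
  if (length(rest)) {
    span[rest] <- vapply(cigar[rest], function(cg) {
      if (cg == "*") return(NA_integer_)
      ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
      if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cg))
        return(NA_integer_)
      n <- as.integer(sub("[A-Z=]$", "", ops))
      op <- substring(ops, nchar(ops))
      sum(n[op %in% c("M", "D", "N", "=", "X")])
    }, integer(1), USE.NAMES = FALSE)
  }
  span
}

parse_sam_lines <- function(lines, lineno) {
  keep <- !startsWith(lines, "@")
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) return(empty_alignments())
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 11L)
    stop("malformed SAM line ", lineno[1], ": fewer than 11 fields")
  bad <- is.na(f[[11L]])
  if (any(bad))
    stop("malformed SAM line ", lineno[which(bad)[1]], ": fewer than 11 fields")
  flag <- suppressWarnings(as.integer(f[[2L]]))
  pos <- suppressWarnings(as.integer(f[[4L]]))
  bad <- is.na(flag) | is.na(pos)
  if (any(bad))
    stop("malformed SAM line ", lineno[which(bad)[1]],
         ": non-numeric FLAG or POS")
  mapped <- bitwAnd(flag, 4L) == 0L
  span <- rep(NA_integer_, length(lines))
  span[mapped] <- cigar_ref_span(f[[6L]][mapped])
  bad <- mapped & is.na(span)
  if (any(bad))
    stop("malformed SAM line ", lineno[which(bad)[1]], ": unusable CIGAR")
  mate <- rep(NA_integer_, length(lines))
  paired <- bitwAnd(flag, 1L) == 1L
  mate[paired & bitwAnd(flag, 64L) > 0L] <- 1L
  mate[paired & bitwAnd(flag, 128L) > 0L] <- 2L
  tok <- split_mate_token(f[[1L]])
  use_tok <- is.na(mate) & !is.na(tok$mate)
  mate[use_tok] <- tok$mate[use_tok]
  pair_id <- tok$pair_id
  out <- data.table::data.table(
    read_id = paste0(pair_id, ifelse(is.na(mate), "", paste0("/", mate))),
    pair_id = pair_id, mate = mate,
    contig = f[[3L]], start = pos - 1L, end = pos - 1L + span,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    keep = mapped)
  out <- out[out$keep][, keep := NULL]
  out
}

parse_bowtie_lines <- function(lines, lineno) {
  if (!length(lines)) return(empty_alignments())
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 5L)
    stop("malformed Bowtie line ", lineno[1], ": fewer than 5 fields")
  bad <- is.na(f[[5L]])
  if (any(bad))
    stop("malformed Bowtie line ", lineno[which(bad)[1]],
         ": fewer than 5 fields")
  strand <- f[[2L]]
  if (!all(strand %in% c("+", "-")))
    stop("malformed Bowtie line ",
         lineno[which(!strand %in% c("+", "-"))[1]], ": bad strand column")
  off <- suppressWarnings(as.integer(f[[4L]]))
  if (anyNA(off))
    stop("malformed Bowtie line ", lineno[which(is.na(off))[1]],
         ": non-numeric offset")
  tok <- split_mate_token(f[[1L]])
  data.table::data.table(
    read_id = f[[1L]], pair_id = tok$pair_id, mate = tok$mate,
    contig = f[[3L]], start = off, end = off + nchar(f[[5L]]),
    strand = strand)
}

parse_blast_lines <- function(lines, lineno) {
  if (!length(lines)) return(empty_alignments())
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 12L)
    stop("malformed BLAST tabular line ", lineno[1], ": fewer than 12 fields")
  bad <- is.na(f[[12L]])
  if (any(bad))
    stop("malformed BLAST tabular line ", lineno[which(bad)[1]],
         ": fewer than 12 fields")
  ss <- suppressWarnings(as.integer(f[[9L]]))
  se <- suppressWarnings(as.integer(f[[10L]]))
  if (anyNA(ss) || anyNA(se))
    stop("malformed BLAST tabular line ",
         lineno[which(is.na(ss) | is.na(se))[1]], ": bad subject coordinates")
  tok <- split_mate_token(f[[1L]])
  data.table::data.table(
    read_id = f[[1L]], pair_id = tok$pair_id, mate = tok$mate,
    contig = f[[2L]],
    start = pmin(ss, se) - 1L, end = pmax(ss, se),
    strand = ifelse(ss <= se, "+", "-"))
}
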