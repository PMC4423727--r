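# External text formats: FASTA contigs, library config, depth table,
# PairStatus metafile, DOT graph export.

#' Read a contig set from FASTA
#'
#' Contigs are returned as a named character vector of upper-case sequences.
#' Ids must be unique and sequences may contain only A, C, G, T, N.
#'
#' @param path FASTA file (plain or gzip).
#' @return named character vector (names = contig ids, first whitespace token
#'   of the header).
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate contig id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  bad <- grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- regmatches(seqs[i], regexpr("[^ACGTN]", seqs[i]))
    stop("non-IUPAC-DNA character '", ch, "' in contig ", ids[i])
  }
  names(seqs) <- ids
  seqs
}

#' Write contigs to FASTA
#'
#' @param contigs named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_contigs <- function(contigs, path, width = 70L) {
  ss <- Biostrings::BStringSet(contigs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a per-contig depth table
#'
#' Two tab-separated columns: contig id, mean fold-coverage. Every contig id
#' must exist in `contigs` when supplied.
#'
#' @param path TSV file.
#' @param contigs optional contig set for id validation.
#' @return named numeric vector of depths.
#' @export
read_depth_table <- function(path, contigs = NULL) {
  dt <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "depth"),
                          colClasses = c("character", "numeric"))
  if (any(dt$depth <= 0)) stop("depths must be > 0")
  if (!is.null(contigs)) {
    miss <- setdiff(dt$contig, names(contigs))
    if (length(miss))
      stop("depth table names unknown contig(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
  }
  stats::setNames(dt$depth, dt$contig)
}

#' Write a per-contig depth table
#' @param depths named numeric vector.
#' @param path output TSV.
#' @export
write_depth_table <- function(depths, path) {
  utils::write.table(
    data.frame(contig = names(depths), depth = unname(depths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a library configuration ("reads info") file
#'
#' SOAPdenovo-style stanza format: each library starts with a `[LIB]` line
#' followed by `key=value` lines. Recognised keys: `name`, `avg_ins` (mean
#' insert size, bp; required), `rank` (scaffolding order, required), `format`
#' (sam/bowtie/blast), and any number of `q1`/`q2`/`f1`/`f2`/`f`/`map` file
#' entries, which are collected as the library's read or alignment files.
#'
#' @param path config file.
#' @param read_len optional read length; a warning is emitted for libraries
#'   whose mean insert is not larger than twice this.
#' @return data.frame with one row per library: name, mean_insert, rank,
#'   format, files (list column); sorted by ascending rank.
#' @export
read_library_config <- function(path, read_len = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  starts <- which(toupper(lines) == "[LIB]")
  if (!length(starts)) {
    warning("no [LIB] stanzas found in ", path)
    return(data.frame(name = character(), mean_insert = integer(),
                      rank = integer(), format = character()))
  }
  bounds <- c(starts, length(lines) + 1L)
  libs <- lapply(seq_along(starts), function(i) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    chunk <- chunk[grepl("=", chunk, fixed = TRUE)]
    key <- tolower(trimws(sub("=.*$", "", chunk)))
    val <- trimws(sub("^[^=]*=", "", chunk))
    kv <- stats::setNames(as.list(val), key)
    if (is.null(kv$avg_ins)) stop("library stanza ", i, " missing avg_ins")
    if (is.null(kv$rank)) stop("library stanza ", i, " missing rank")
    files <- val[key %in% c("q1", "q2", "f1", "f2", "f", "q", "map")]
    list(name = kv$name %||% paste0("lib", i),
         mean_insert = as.integer(kv$avg_ins),
         rank = as.integer(kv$rank),
         format = tolower(kv$format %||% "sam"),
         files = files)
  })
  out <- data.frame(
    name = vapply(libs, `[[`, "", "name"),
    mean_insert = vapply(libs, `[[`, 0L, "mean_insert"),
    rank = vapply(libs, `[[`, 0L, "rank"),
    format = vapply(libs, `[[`, "", "format"),
    stringsAsFactors = FALSE)
  out$files <- lapply(libs, `[[`, "files")
  if (any(out$rank < 1L)) stop("library rank must be >= 1")
  if (any(out$mean_insert <= 0L)) stop("avg_ins must be positive")
  if (!is.null(read_len) && any(out$mean_insert <= 2L * read_len))
    warning("library mean insert <= 2 x read length: ",
            paste(out$name[out$mean_insert <= 2L * read_len], collapse = ", "))
  out[order(out$rank), , drop = FALSE]
}

# ---- PairStatus -------------------------------------------------------------

PAIR_STATUSES <- c("LINK", "SAME_CONTIG", "ONE_END_UNMAPPED", "BOTH_UNMAPPED",
                   "MULTIPLY_MAPPED_SUPPRESSED", "REPEAT_EXCLUDED", "REJECT")

#' Write the PairStatus metafile
#'
#' One tab-delimited line per input pair, in input order: pair id, status,
#' then up to two detail columns (linked contig ids, or the contig and
#' intra-contig span for SAME_CONTIG pairs).
#'
#' @param records data.frame with columns pair_id, status, detail1, detail2
#'   (details optional).
#' @param path output file.
#' @export
write_pair_status <- function(records, path) {
  stopifnot(all(c("pair_id", "status") %in% names(records)))
  if (!all(records$status %in% PAIR_STATUSES))
    stop("unknown status value(s): ",
         paste(setdiff(unique(records$status), PAIR_STATUSES), collapse = ", "))
  d1 <- as.character(records$detail1 %||% rep("", nrow(records)))
  d2 <- as.character(records$detail2 %||% rep("", nrow(records)))
  d1[is.na(d1)] <- ""; d2[is.na(d2)] <- ""
  lines <- paste(records$pair_id, records$status, d1, d2, sep = "\t")
  lines <- sub("\t+$", "", lines)
  writeLines(lines, path)
  invisible(path)
}

# ---- DOT export -------------------------------------------------------------

#' Export a scaffold graph in DOT format
#'
#' Nodes are contigs; each scaffolding edge is rendered with its end tags,
#' support weight, and gap estimate. Edges filtered out by the minimum-support
#' rule can optionally be rendered as dashed edges.
#'
#' @param graph a `scaffold_graph` object.
#' @param path output file.
#' @param show_excluded render excluded edges dashed?
#' @param highlight optional character vector of contig ids to mark (filled).
#' @export
write_dot <- function(graph, path, show_excluded = FALSE, highlight = NULL) {
  stopifnot(inherits(graph, "scaffold_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("graph scaffold {", con)
  writeLines("  node [shape=box];", con)
  for (i in seq_len(nrow(graph$contigs))) {
    id <- graph$contigs$id[i]
    attr <- sprintf("label=\"%s\\n%d bp\"", id, graph$contigs$length[i])
    if (!is.null(highlight) && id %in% highlight)
      attr <- paste0(attr, ", style=filled, fillcolor=lightblue")
    writeLines(sprintf("  \"%s\" [%s];", id, attr), con)
  }
  ed <- graph$edges
  if (!is.null(ed) && nrow(ed)) {
    keep <- if (show_excluded) rep(TRUE, nrow(ed)) else !ed$excluded
    ed <- ed[keep, , drop = FALSE]
    if (nrow(ed)) {
      style <- ifelse(ed$excluded, ", style=dashed", "")
      writeLines(sprintf(
        "  \"%s\" -- \"%s\" [label=\"%s-%s w=%d g=%.0f\"%s];",
        ed$c_a, ed$c_b, ed$e_a, ed$e_b, ed$weight, ed$gap, style), con)
    }
  }
  writeLines("}", con)
  invisible(path)
}
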