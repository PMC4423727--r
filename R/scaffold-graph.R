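# The weighted bidirected scaffold graph. Each edge joins two contig *ends*
# (5' or 3'), thereby fixing a relative orientation for both contigs; its
# weight is the number of supporting read pairs and its gap estimate the mean
# of the per-pair insert-implied distances (negative means overlap).

#' Interpret one read pair as scaffolding evidence
#'
#' Each mapped end nominates the contig end its unsequenced mate fragment
#' extends toward: a forward-strand hit nominates the 3' end of its contig, a
#' reverse-strand hit the 5' end. The implied gap between the two nominated
#' ends is `mean_insert - tail_1 - tail_2`, where a tail is the distance from
#' the alignment's outer read edge to the nominated contig end (the read
#' itself is included in the tail).
#'
#' @param aln_1,aln_2 single-row alignment records (data.frame/list with
#'   contig, start, end, strand).
#' @param mean_insert library mean insert size (bp).
#' @param contigs contig set (for contig lengths).
#' @return a list with `status` one of "LINK", "SAME_CONTIG", "REJECT"; for
#'   LINK also end_a/end_b (list(contig, end)) and gap; for SAME_CONTIG the
#'   observed end-to-end span.
#' @export
pair_to_edge <- function(aln_1, aln_2, mean_insert, contigs) {
  p <- pair_evidence(
    data.table::data.table(
      contig_x = aln_1$contig, start_x = aln_1$start, end_x = aln_1$end,
      strand_x = aln_1$strand, contig_y = aln_2$contig, start_y = aln_2$start,
      end_y = aln_2$end, strand_y = aln_2$strand),
    mean_insert, nchar(contigs))
  if (p$status == "SAME_CONTIG")
    return(list(status = "SAME_CONTIG", span = p$span))
  if (p$status == "REJECT") return(list(status = "REJECT"))
  list(status = "LINK",
       end_a = list(contig = p$c_a, end = p$e_a),
       end_b = list(contig = p$c_b, end = p$e_b),
       gap = p$gap)
}

# vectorised core of pair_to_edge over a table of paired placements
pair_evidence <- function(pairs, mean_insert, contig_len) {
  n <- nrow(pairs)
  lx <- contig_len[pairs$contig_x]
  ly <- contig_len[pairs$contig_y]
  ex <- ifelse(pairs$strand_x == "+", "3p", "5p")
  ey <- ifelse(pairs$strand_y == "+", "3p", "5p")
  tailx <- ifelse(pairs$strand_x == "+", lx - pairs$start_x, pairs$end_x)
  taily <- ifelse(pairs$strand_y == "+", ly - pairs$start_y, pairs$end_y)
  gap <- mean_insert - tailx - taily
  same <- pairs$contig_x == pairs$contig_y
  # same contig: innie geometry requires opposite strands with the forward
  # read upstream of the reverse read
  fs <- ifelse(pairs$strand_x == "+", pairs$start_x, pairs$start_y)
  re <- ifelse(pairs$strand_x == "+", pairs$end_y, pairs$end_x)
  ok_same <- same & (pairs$strand_x != pairs$strand_y) & (fs < re)
  status <- rep("LINK", n)
  status[same & ok_same] <- "SAME_CONTIG"
  status[same & !ok_same] <- "REJECT"
  # canonical endpoint order: lexicographically smaller contig first
  swap <- !same & (pairs$contig_y < pairs$contig_x)
  res <- data.table::data.table(
    status = status,
    c_a = ifelse(swap, pairs$contig_y, pairs$contig_x),
    e_a = ifelse(swap, ey, ex),
    c_b = ifelse(swap, pairs$contig_x, pairs$contig_y),
    e_b = ifelse(swap, ex, ey),
    gap = as.numeric(gap),
    span = as.numeric(re - fs))
  res$c_a[same] <- pairs$contig_x[same]
  res$c_b[same] <- pairs$contig_x[same]
  res
}

#' Build the scaffold graph from paired alignments
#'
#' Pairs both ends of which are uniquely mapped contribute one scaffolding
#' edge each; identical (end, end) links are aggregated into a single weighted
#' edge whose gap estimate is the mean of the per-pair distances. Every input
#' pair receives exactly one PairStatus record.
#'
#' @param alignments alignment table from [read_alignments()] (one or more
#'   libraries of the same rank, rbind-ed).
#' @param contigs contig set.
#' @param mean_insert library mean insert size (bp).
#' @param allow_multimapped include pairs with multiply-mapped ends? Default
#'   FALSE: such pairs are suppressed (recorded as
#'   MULTIPLY_MAPPED_SUPPRESSED). When TRUE every reported placement pair of a
#'   multi-mapped read contributes.
#' @return list with `graph` (a `scaffold_graph`) and `pair_status`
#'   (data.table: pair_id, status, detail1, detail2).
#' @export
build_scaffold_graph <- function(alignments, contigs, mean_insert,
                                 allow_multimapped = FALSE) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  aln <- data.table::as.data.table(alignments)
  clen <- nchar(contigs)
  all_pairs <- unique(aln$pair_id)
  status <- data.table::data.table(pair_id = all_pairs, status = "",
                                   detail1 = "", detail2 = "")
  data.table::setkey(status, pair_id)

  m1 <- aln[mate == 1L]
  m2 <- aln[mate == 2L]
  have1 <- unique(m1$pair_id)
  have2 <- unique(m2$pair_id)
  both <- intersect(have1, have2)
  one <- setdiff(union(have1, have2), both)
  status[.(one), status := "ONE_END_UNMAPPED"]
  status[.(setdiff(all_pairs, union(have1, have2))), status := "BOTH_UNMAPPED"]

  if (!allow_multimapped) {
    multi <- unique(aln[mult > 1L]$pair_id)
    supp <- intersect(both, multi)
    status[.(supp), status := "MULTIPLY_MAPPED_SUPPRESSED"]
    both <- setdiff(both, supp)
    m1 <- m1[mult == 1L]
    m2 <- m2[mult == 1L]
  }
  edges <- empty_edge_table()
  if (length(both)) {
    j <- merge(m1[pair_id %in% both],
               m2[pair_id %in% both],
               by = "pair_id", suffixes = c("_x", "_y"),
               allow.cartesian = TRUE)
    ev <- pair_evidence(j, mean_insert, clen)
    ev[, pair_id := j$pair_id]
    same <- ev[status == "SAME_CONTIG"]
    if (nrow(same)) {
      agg <- same[, .(c = c_a[1], sp = span[1]), by = pair_id]
      status[.(agg$pair_id),
             `:=`(status = "SAME_CONTIG", detail1 = agg$c,
                  detail2 = as.character(round(agg$sp)))]
    }
    rej <- ev[status == "REJECT"]
    if (nrow(rej)) {
      left <- setdiff(unique(rej$pair_id), unique(ev[status != "REJECT"]$pair_id))
      status[.(left), status := "REJECT"]
    }
    links <- ev[status == "LINK"]
    if (nrow(links)) {
      agg <- links[, .(lc1 = c_a[1], lc2 = c_b[1]), by = pair_id]
      status[.(agg$pair_id),
             `:=`(status = "LINK", detail1 = agg$lc1, detail2 = agg$lc2)]
      edges <- links[, .(weight = .N, gap = mean(gap)),
                     by = .(c_a, e_a, c_b, e_b)]
    }
  }
  data.table::setorder(edges, c_a, e_a, c_b, e_b)
  edges[, excluded := FALSE]
  g <- structure(list(
    contigs = data.frame(id = names(contigs), length = unname(clen),
                         stringsAsFactors = FALSE),
    edges = edges,
    repeats = character(),
    min_support = 1L), class = "scaffold_graph")
  idx <- data.table::chmatch(all_pairs, status$pair_id)
  status_out <- status[idx]
  list(graph = g, pair_status = status_out[])
}

#' Construct a scaffold graph from an explicit edge list
#'
#' Programmatic constructor used for testing and for building graphs from
#' sources other than read alignments. Endpoints are canonicalised
#' (lexicographically smaller contig first) and duplicate links aggregate.
#'
#' @param edges data.frame with columns c_a, e_a ("5p"/"3p"), c_b, e_b, and
#'   optionally weight (default 1) and gap (default 0).
#' @param contig_lengths named integer vector of contig lengths.
#' @return a `scaffold_graph`.
#' @export
scaffold_graph <- function(edges, contig_lengths) {
  ed <- data.table::as.data.table(edges)
  if (!nrow(ed)) ed <- empty_edge_table()
  else {
    if (is.null(ed$weight)) ed[, weight := 1L]
    if (is.null(ed$gap)) ed[, gap := 0]
    stopifnot(all(c(ed$c_a, ed$c_b) %in% names(contig_lengths)),
              all(c(ed$e_a, ed$e_b) %in% c("5p", "3p")),
              all(ed$c_a != ed$c_b))
    swap <- ed$c_b < ed$c_a
    tmp_c <- ed$c_a[swap]; tmp_e <- ed$e_a[swap]
    ed[swap, `:=`(c_a = c_b, e_a = e_b)]
    ed$c_b[swap] <- tmp_c; ed$e_b[swap] <- tmp_e
    ed <- ed[, .(weight = sum(weight), gap = stats::weighted.mean(gap, weight)),
             by = .(c_a, e_a, c_b, e_b)]
    ed[, excluded := FALSE]
    data.table::setorder(ed, c_a, e_a, c_b, e_b)
  }
  structure(list(
    contigs = data.frame(id = names(contig_lengths),
                         length = as.integer(unname(contig_lengths)),
                         stringsAsFactors = FALSE),
    edges = ed, repeats = character(), min_support = 1L),
    class = "scaffold_graph")
}

empty_edge_table <- function() {
  data.table::data.table(c_a = character(), e_a = character(),
                         c_b = character(), e_b = character(),
                         weight = integer(), gap = numeric(),
                         excluded = logical())
}

#' @export
print.scaffold_graph <- function(x, ...) {
  ne <- nrow(x$edges)
  na <- if (ne) sum(!x$edges$excluded) else 0L
  cat("scaffold graph:", nrow(x$contigs), "contigs,", ne, "edges (",
      na, "active ),", length(x$repeats), "repeat-flagged\n")
  invisible(x)
}

#' Apply a minimum edge-support threshold
#'
#' Edges supported by fewer than `min_support` pairs are marked excluded:
#' they are invisible to every downstream query but retained for dashed
#' rendering in DOT export.
#'
#' @param graph a `scaffold_graph`.
#' @param min_support minimum number of supporting pairs (default 2).
#' @return the filtered graph.
#' @export
apply_min_support <- function(graph, min_support = 2L) {
  stopifnot(inherits(graph, "scaffold_graph"))
  if (min_support < 1L) stop("min_support must be >= 1")
  if (nrow(graph$edges))
    graph$edges[, excluded := weight < min_support]
  graph$min_support <- as.integer(min_support)
  graph
}

# active (non-excluded) edges not touching repeat-flagged contigs
active_edges <- function(graph) {
  ed <- graph$edges
  if (!nrow(ed)) return(ed)
  ed <- ed[!ed$excluded]
  if (length(graph$repeats))
    ed <- ed[!(ed$c_a %in% graph$repeats | ed$c_b %in% graph$repeats)]
  ed
}

#' Edges incident to one contig end
#'
#' @param graph a `scaffold_graph`.
#' @param contig contig id.
#' @param end "5p" or "3p".
#' @return the incident active edges (data.table).
#' @export
end_edges <- function(graph, contig, end) {
  ed <- active_edges(graph)
  ed[(ed$c_a == contig & ed$e_a == end) | (ed$c_b == contig & ed$e_b == end)]
}

# per-(contig,end) degree table over active edges
end_degree_table <- function(graph) {
  ed <- active_edges(graph)
  if (!nrow(ed)) {
    return(data.table::data.table(contig = character(), end = character(),
                                  degree = integer()))
  }
  long <- data.table::rbindlist(list(
    ed[, .(contig = c_a, end = e_a)],
    ed[, .(contig = c_b, end = e_b)]))
  long[, .(degree = .N), by = .(contig, end)]
}

#' Flag repeat-like contigs
#'
#' A contig is flagged when its total vertex degree exceeds `degree_factor`
#' times the median degree over linked contigs of length >= 100 bp, or (when
#' depths are available) its depth exceeds `depth_factor` times the modal
#' depth. Flagged contigs are excluded from bubbles, chains and output.
#'
#' @param graph a `scaffold_graph`.
#' @param depths optional named depth vector.
#' @param degree_factor,depth_factor positive multipliers (defaults 5 and 3;
#'   the modal depth of a diploid contig set is typically the haploid mode,
#'   so the depth threshold must clear diploid-depth homotigs).
#' @return the graph with `repeats` set.
#' @export
flag_repeats <- function(graph, depths = NULL, degree_factor = 5,
                         depth_factor = 3) {
  stopifnot(inherits(graph, "scaffold_graph"),
            degree_factor > 0, depth_factor > 0)
  graph$repeats <- character()
  degt <- end_degree_table(graph)
  flagged <- character()
  if (nrow(degt)) {
    tot <- degt[, .(degree = sum(degree)), by = contig]
    len <- stats::setNames(graph$contigs$length, graph$contigs$id)
    eligible <- tot[len[tot$contig] >= 100L]
    med <- if (nrow(eligible)) stats::median(eligible$degree) else NA_real_
    if (!is.na(med) && med > 0)
      flagged <- tot$contig[tot$degree > degree_factor * med]
  }
  if (!is.null(depths) && length(depths)) {
    len <- stats::setNames(graph$contigs$length, graph$contigs$id)
    keep <- names(depths)[len[names(depths)] >= 100L]
    if (length(keep)) {
      m <- depth_mode(depths[keep])
      flagged <- union(flagged, names(depths)[depths > depth_factor * m])
    }
  }
  graph$repeats <- sort(intersect(flagged, graph$contigs$id))
  graph
}
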