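# Heterozygous bubbles in the scaffold graph. A bubble is a pair of candidate
# homologous contigs (a, b) flanked by a common contig c1 on one side and a
# different common contig c2 on the other. Perfect bubbles -- where a and b
# each have exactly one scaffolding per direction and the flank ends carry no
# other edges -- are the classifier's training source; imperfect candidates
# (missing or conflicted edges) are scored and classified.

# per-end adjacency in long form: one row per (contig, end, partner, p_end, weight)
end_adjacency <- function(graph) {
  ed <- active_edges(graph)
  if (!nrow(ed)) {
    return(data.table::data.table(contig = character(), end = character(),
                                  partner = character(), p_end = character(),
                                  weight = integer(), gap = numeric()))
  }
  data.table::rbindlist(list(
    ed[, .(contig = c_a, end = e_a, partner = c_b, p_end = e_b, weight, gap)],
    ed[, .(contig = c_b, end = e_b, partner = c_a, p_end = e_a, weight, gap)]))
}

#' Find perfect bubbles
#'
#' A perfect bubble consists of contigs (c1, a, b, c2) such that a and b each
#' have exactly one scaffolding in each direction, those scaffoldings lead to
#' the common flanks c1 and c2 (attaching at one consistent end of each
#' flank), and the involved flank ends carry no other conflicting
#' scaffoldings. Two perfect bubbles may share a flank contig but cannot
#' otherwise overlap.
#'
#' @param graph a `scaffold_graph` (min-support filter already applied;
#'   repeat-flagged contigs are ignored automatically).
#' @return data.frame with one row per bubble: c1, a, b, c2, flank end tags
#'   (e1, e2: the ends of c1/c2 facing the bubble), heterotig end tags
#'   (a_end1 = a's end facing c1, b_end1 likewise), the four edge weights and
#'   gap estimates. Heterotig order within a row and row order are
#'   lexicographic.
#' @export
find_perfect_bubbles <- function(graph) {
  adj <- end_adjacency(graph)
  if (!nrow(adj)) return(empty_bubble_table())
  deg <- adj[, .(degree = .N), by = .(contig, end)]
  # heterotig candidates: exactly one edge on each end
  d2 <- data.table::dcast(deg, contig ~ end, value.var = "degree", fill = 0L)
  if (!all(c("5p", "3p") %in% names(d2))) return(empty_bubble_table())
  hets <- d2$contig[d2[["5p"]] == 1L & d2[["3p"]] == 1L]
  if (length(hets) < 2L) return(empty_bubble_table())
  one <- adj[contig %in% hets]
  w5 <- one[end == "5p"]; w3 <- one[end == "3p"]
  data.table::setkey(w5, contig); data.table::setkey(w3, contig)
  cand <- merge(w5, w3, by = "contig", suffixes = c("_5", "_3"))
  # both flanks must be distinct contigs, different from the heterotig pair
  cand <- cand[partner_5 != partner_3]
  # canonical flank key: unordered pair of flank (contig,end)
  k5 <- end_key(cand$partner_5, cand$p_end_5)
  k3 <- end_key(cand$partner_3, cand$p_end_3)
  swap <- k3 < k5
  cand[, `:=`(fk1 = ifelse(swap, k3, k5), fk2 = ifelse(swap, k5, k3))]
  cand[, fkey := paste(fk1, fk2, sep = "|")]
  grp <- split(seq_len(nrow(cand)), cand$fkey)
  degk <- stats::setNames(deg$degree, end_key(deg$contig, deg$end))
  rows <- list()
  for (idx in grp) {
    if (length(idx) != 2L) next   # flank shared by != 2 single-single contigs
    r <- cand[idx]
    ab <- sort(r$contig)
    r <- r[match(ab, r$contig)]
    # flanks, oriented so c1 is a's 5'-side partner
    c1 <- r$partner_5[1]; e1 <- r$p_end_5[1]
    c2 <- r$partner_3[1]; e2 <- r$p_end_3[1]
    if (any(ab %in% c(c1, c2))) next
    # flank-end purity: exactly the two bubble edges on each flank end
    if (degk[end_key(c1, e1)] != 2L || degk[end_key(c2, e2)] != 2L) next
    b_to_c1_5 <- r$partner_5[2] == c1
    rows[[length(rows) + 1L]] <- data.frame(
      c1 = c1, a = ab[1], b = ab[2], c2 = c2, e1 = e1, e2 = e2,
      a_end1 = "5p", a_end2 = "3p",
      b_end1 = if (b_to_c1_5) "5p" else "3p",
      b_end2 = if (b_to_c1_5) "3p" else "5p",
      w_c1a = r$weight_5[1], w_c1b = if (b_to_c1_5) r$weight_5[2] else r$weight_3[2],
      w_ac2 = r$weight_3[1], w_bc2 = if (b_to_c1_5) r$weight_3[2] else r$weight_5[2],
      g_c1a = r$gap_5[1], g_c1b = if (b_to_c1_5) r$gap_5[2] else r$gap_3[2],
      g_ac2 = r$gap_3[1], g_bc2 = if (b_to_c1_5) r$gap_3[2] else r$gap_5[2],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_bubble_table())
  out <- do.call(rbind, rows)
  # canonical row identity: Bubble(c1,a,b,c2) == Bubble(c2,b,a,c1); orient so
  # the lexicographically smaller flank comes first
  flip <- out$c2 < out$c1
  if (any(flip)) {
    f <- out[flip, ]
    out[flip, c("c1", "c2", "e1", "e2")] <- f[, c("c2", "c1", "e2", "e1")]
    out[flip, c("a_end1", "a_end2")] <- f[, c("a_end2", "a_end1")]
    out[flip, c("b_end1", "b_end2")] <- f[, c("b_end2", "b_end1")]
    out[flip, c("w_c1a", "w_ac2")] <- f[, c("w_ac2", "w_c1a")]
    out[flip, c("w_c1b", "w_bc2")] <- f[, c("w_bc2", "w_c1b")]
    out[flip, c("g_c1a", "g_ac2")] <- f[, c("g_ac2", "g_c1a")]
    out[flip, c("g_c1b", "g_bc2")] <- f[, c("g_bc2", "g_c1b")]
  }
  out <- out[!duplicated(out[, c("c1", "a", "b", "c2")]), , drop = FALSE]
  out <- out[order(out$c1, out$a, out$b, out$c2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_bubble_table <- function() {
  data.frame(c1 = character(), a = character(), b = character(),
             c2 = character(), e1 = character(), e2 = character(),
             a_end1 = character(), a_end2 = character(),
             b_end1 = character(), b_end2 = character(),
             w_c1a = integer(), w_c1b = integer(), w_ac2 = integer(),
             w_bc2 = integer(), g_c1a = numeric(), g_c1b = numeric(),
             g_ac2 = numeric(), g_bc2 = numeric(), stringsAsFactors = FALSE)
}

#' Enumerate imperfect bubbles ordered by perfectness
#'
#' Candidates are seeded from every contig pair that shares a flank neighbour
#' at one consistent flank end; the opposite flank is then completed with the
#' best shared partner available. Candidates that fail the perfect-bubble
#' definition -- through missing edges (including an entirely absent second
#' flank) or conflicting extra scaffoldings -- are scored and returned in
#' decreasing order of perfectness: fewer missing edges, then fewer
#' conflicts, then higher total support, with a lexicographic contig-id
#' tie-break.
#'
#' @param graph a `scaffold_graph`.
#' @param perfect output of [find_perfect_bubbles()]; its heterotigs and
#'   pairs are never re-offered.
#' @param min_edges minimum number of the four bubble edges that must be
#'   present (default 2; set to 4 to restrict to fully-edged but conflicted
#'   candidates).
#' @return data.frame like [find_perfect_bubbles()] plus columns
#'   missing_edges, conflict_count, total_support. Missing edges have weight
#'   0 and gap NA; a missing flank leaves c2 = NA.
#' @export
enumerate_imperfect_bubbles <- function(graph, perfect = NULL, min_edges = 2L) {
  adj <- end_adjacency(graph)
  if (!nrow(adj)) return(empty_imperfect_table())
  taken <- if (!is.null(perfect) && nrow(perfect))
    unique(c(perfect$a, perfect$b)) else character()
  deg <- adj[, .(degree = .N), by = .(contig, end)]
  degk <- stats::setNames(deg$degree, end_key(deg$contig, deg$end))
  # seed pairs: two contigs attached to the same flank (contig,end)
  rows <- list()
  fl <- split(adj, end_key(adj$partner, adj$p_end))
  for (fkey in names(fl)) {
    grp <- fl[[fkey]]
    grp <- grp[!(grp$contig %in% taken)]
    if (nrow(grp) < 2L) next
    cmb <- utils::combn(seq_len(nrow(grp)), 2L)
    for (k in seq_len(ncol(cmb))) {
      ra <- grp[cmb[1L, k]]; rb <- grp[cmb[2L, k]]
      if (ra$contig == rb$contig) next
      cands <- score_candidate(graph, adj, degk, ra, rb)
      for (cand in cands) {
        if ((4L - cand$missing_edges) >= min_edges &&
            !(cand$missing_edges == 0L && cand$conflict_count == 0L))
          rows[[length(rows) + 1L]] <- cand
      }
    }
  }
  if (!length(rows)) return(empty_imperfect_table())
  out <- do.call(rbind, rows)
  if (!is.null(perfect) && nrow(perfect)) {
    pk <- paste(perfect$a, perfect$b, sep = "|")
    out <- out[!(paste(out$a, out$b, sep = "|") %in% pk), , drop = FALSE]
  }
  # a pair may admit several constructions (different flank seeds); all are
  # returned in decreasing perfectness. During acceptance the occupancy rule
  # admits at most one construction per pair, and a pair whose best
  # construction conflicts still gets a chance with its next one.
  out <- unique(out)
  out <- out[order(out$missing_edges, out$conflict_count, -out$total_support,
                   out$a, out$b, out$c1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_imperfect_table <- function() {
  cbind(empty_bubble_table(),
        data.frame(missing_edges = integer(), conflict_count = integer(),
                   total_support = integer()))
}

# assemble and score the candidate constructions arising from two seed
# attachments to a common flank (ra, rb are single rows of the adjacency
# table sharing partner/p_end). Returns a list of candidate rows: one per
# shared far flank; when none is shared, one per single-sided far-flank
# option (one missing edge) or a flankless construction (two missing edges).
score_candidate <- function(graph, adj, degk, ra, rb) {
  c1 <- ra$partner; e1 <- ra$p_end
  a <- min(ra$contig, rb$contig); b <- max(ra$contig, rb$contig)
  if (ra$contig != a) { tmp <- ra; ra <- rb; rb <- tmp }
  a_end1 <- ra$end; b_end1 <- rb$end
  a_end2 <- other_end(a_end1); b_end2 <- other_end(b_end1)
  # candidate far flanks: partners on the opposite ends
  fa <- adj[contig == a & end == a_end2]
  fb <- adj[contig == b & end == b_end2]
  shared <- intersect(end_key(fa$partner, fa$p_end),
                      end_key(fb$partner, fb$p_end))
  shared <- setdiff(shared, end_key(c(c1, a, b), rep(c("5p", "3p"), each = 3)))
  shared <- setdiff(shared, end_key(c1, e1))
  w <- function(tbl, key) tbl$weight[end_key(tbl$partner, tbl$p_end) == key][1]
  g <- function(tbl, key) tbl$gap[end_key(tbl$partner, tbl$p_end) == key][1]
  dg <- function(key) { v <- degk[key]; if (is.na(v)) 0L else as.integer(v) }
  finish <- function(c2, e2, edges_w, edges_g, missing) {
    # conflicts: extra active edges beyond the bubble's own on a's and b's
    # ends and on the flank ends facing the bubble
    conf <- (dg(end_key(a, a_end1)) - 1L) + (dg(end_key(b, b_end1)) - 1L)
    conf <- conf + max(dg(end_key(c1, e1)) - 2L, 0L)
    if (missing == 0L) {
      conf <- conf + (dg(end_key(a, a_end2)) - 1L) +
        (dg(end_key(b, b_end2)) - 1L) + max(dg(end_key(c2, e2)) - 2L, 0L)
    } else if (missing == 1L) {
      has_a <- edges_w[3] > 0L
      conf <- conf +
        (if (has_a) dg(end_key(a, a_end2)) - 1L else dg(end_key(a, a_end2))) +
        (if (!has_a) dg(end_key(b, b_end2)) - 1L else dg(end_key(b, b_end2)))
      conf <- conf + max(dg(end_key(c2, e2)) - 1L, 0L)
    } else {
      conf <- conf + dg(end_key(a, a_end2)) + dg(end_key(b, b_end2))
    }
    data.frame(c1 = c1, a = a, b = b, c2 = c2, e1 = e1, e2 = e2,
               a_end1 = a_end1, a_end2 = a_end2,
               b_end1 = b_end1, b_end2 = b_end2,
               w_c1a = edges_w[1], w_c1b = edges_w[2],
               w_ac2 = edges_w[3], w_bc2 = edges_w[4],
               g_c1a = edges_g[1], g_c1b = edges_g[2],
               g_ac2 = edges_g[3], g_bc2 = edges_g[4],
               missing_edges = missing,
               conflict_count = as.integer(conf),
               total_support = as.integer(sum(edges_w)),
               stringsAsFactors = FALSE)
  }
  out <- list()
  if (length(shared)) {
    out <- lapply(sort(shared), function(key2) {
      c2 <- sub(":[35]p$", "", key2)
      e2 <- sub("^.*:", "", key2)
      finish(c2, e2,
             c(ra$weight, rb$weight, w(fa, key2), w(fb, key2)),
             c(ra$gap, rb$gap, g(fa, key2), g(fb, key2)), 0L)
    })
  } else {
    # no shared far flank: one candidate per single-sided partner (one
    # missing edge)
    pool <- data.table::rbindlist(list(fa, fb))
    pool <- pool[!(pool$partner %in% c(c1, a, b))]
    if (nrow(pool)) {
      pool <- pool[order(-pool$weight, pool$partner, pool$p_end)]
      out <- lapply(seq_len(nrow(pool)), function(i) {
        c2 <- pool$partner[i]; e2 <- pool$p_end[i]
        from_a <- pool$contig[i] == a
        key2 <- end_key(c2, e2)
        finish(c2, e2,
               c(ra$weight, rb$weight,
                 if (from_a) w(fa, key2) else 0L,
                 if (from_a) 0L else w(fb, key2)),
               c(ra$gap, rb$gap,
                 if (from_a) g(fa, key2) else NA_real_,
                 if (from_a) NA_real_ else g(fb, key2)), 1L)
      })
    }
  }
  # the flankless construction is always offered as a conservative fallback:
  # when every far-flank hypothesis conflicts with included edges, the pair
  # can still be accepted as a partial (one-flank) bubble
  out[[length(out) + 1L]] <-
    finish(NA_character_, NA_character_,
           c(ra$weight, rb$weight, 0L, 0L),
           c(ra$gap, rb$gap, NA_real_, NA_real_), 2L)
  out
}
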