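# Bubble acceptance, greedy chain linking, haplotype phasing of bubble
# chains, and emission of the two linear haploid scaffolds.
#
# The included-edge set enforces the scaffolding occupancy rule: within the
# iterative selection, a contig may be scaffolded only once in the 5'
# direction and once in the 3' direction. A bubble's two parallel edges on a
# flank end count as a single scaffolding of that end (the bubble is both
# candidate reconstructions of one locus).

#' Create an empty included-edge set
#' @return an `included_set` object.
#' @export
new_included_set <- function() {
  structure(list(items = list(), occ = character()), class = "included_set")
}

# end keys a bubble occupies (ends of its present edges); heterotig outer
# ends of missing edges stay free but are blocked from greedy linking
bubble_keys <- function(br) {
  keys <- c(end_key(br$c1, br$e1),
            end_key(br$a, br$a_end1), end_key(br$b, br$b_end1))
  if (!is.na(br$c2) && (br$w_ac2 > 0L || br$w_bc2 > 0L))
    keys <- c(keys, end_key(br$c2, br$e2))
  if (br$w_ac2 > 0L) keys <- c(keys, end_key(br$a, br$a_end2))
  if (br$w_bc2 > 0L) keys <- c(keys, end_key(br$b, br$b_end2))
  unique(keys)
}

add_item <- function(included, item, keys) {
  i <- length(included$items) + 1L
  included$items[[i]] <- item
  included$occ[keys] <- i
  included
}

#' Accept bubbles under the conflict rule
#'
#' Perfect bubbles are accepted first (they can never conflict with each
#' other). Classified imperfect bubbles are then considered in the given
#' (decreasing-perfectness) order; a bubble is accepted only if none of its
#' constituent edges conflicts with -- or is -- an edge already included.
#'
#' @param perfect perfect-bubble table.
#' @param imperfect classified-positive imperfect bubbles, already ordered
#'   by decreasing perfectness.
#' @param included an `included_set` (default fresh).
#' @return list: `included` (updated set), `accepted` (combined bubble table
#'   with columns origin = perfect/imperfect and accepted flag for the
#'   imperfect candidates).
#' @export
accept_bubbles <- function(perfect, imperfect = NULL, included = NULL) {
  if (is.null(included)) included <- new_included_set()
  acc <- list()
  core <- names(empty_bubble_table())
  if (!is.null(perfect) && nrow(perfect)) {
    for (i in seq_len(nrow(perfect))) {
      br <- perfect[i, ]
      keys <- bubble_keys(br)
      if (any(keys %in% names(included$occ)))
        stop("internal: perfect bubbles conflict at ",
             paste(intersect(keys, names(included$occ)), collapse = ","))
      included <- add_item(included,
                           list(type = "bubble", bubble = br,
                                origin = "perfect"), keys)
      acc[[length(acc) + 1L]] <- cbind(br[core], origin = "perfect")
    }
  }
  if (!is.null(imperfect) && nrow(imperfect)) {
    for (i in seq_len(nrow(imperfect))) {
      br <- imperfect[i, ]
      keys <- bubble_keys(br)
      if (any(keys %in% names(included$occ))) next
      included <- add_item(included,
                           list(type = "bubble", bubble = br,
                                origin = "imperfect"), keys)
      acc[[length(acc) + 1L]] <- cbind(br[core], origin = "imperfect")
    }
  }
  accepted <- if (length(acc)) do.call(rbind, acc)
              else cbind(empty_bubble_table(), origin = character())
  rownames(accepted) <- NULL
  list(included = included, accepted = accepted)
}

#' Greedily link remaining scaffoldings
#'
#' Remaining active edges of the current library rank are considered in
#' decreasing order of support weight (ties broken lexicographically by
#' endpoint); an edge is included only when both its contig ends are still
#' unscaffolded. Ends belonging to accepted-bubble heterotigs and
#' repeat-flagged contigs are never linked.
#'
#' @param graph the rank's `scaffold_graph`.
#' @param included the `included_set` carried across iterations.
#' @param blocked_ends additional end keys that must not be linked
#'   (heterotig ends of accepted bubbles).
#' @return the updated `included_set`.
#' @export
greedy_link <- function(graph, included, blocked_ends = character()) {
  ed <- active_edges(graph)
  if (!nrow(ed)) return(included)
  ed <- ed[order(-ed$weight, ed$c_a, ed$e_a, ed$c_b, ed$e_b)]
  for (i in seq_len(nrow(ed))) {
    k1 <- end_key(ed$c_a[i], ed$e_a[i])
    k2 <- end_key(ed$c_b[i], ed$e_b[i])
    if (k1 %in% names(included$occ) || k2 %in% names(included$occ)) next
    if (k1 %in% blocked_ends || k2 %in% blocked_ends) next
    included <- add_item(included,
                         list(type = "edge", c_a = ed$c_a[i], e_a = ed$e_a[i],
                              c_b = ed$c_b[i], e_b = ed$e_b[i],
                              weight = ed$weight[i], gap = ed$gap[i]),
                         c(k1, k2))
  }
  included
}

# all end keys of heterotigs inside accepted bubbles
heterotig_end_keys <- function(accepted) {
  if (is.null(accepted) || !nrow(accepted)) return(character())
  hets <- unique(c(accepted$a, accepted$b))
  as.character(outer(hets, c("5p", "3p"), end_key))
}

#' Build scaffold chains from the included-edge set
#'
#' Included bubbles and greedy edges pair up contig ends; because each end is
#' used at most once, the connected structures are simple paths (rare cycles
#' are broken deterministically before the lexicographically smallest member
#' contig). Each chain is an ordered alternation of oriented contigs and
#' heterotig-pair (bubble) slots; contigs in no chain become singletons.
#'
#' @param included an `included_set`.
#' @param contigs contig set (all non-repeat contigs are emitted somewhere).
#' @param repeats repeat-flagged contig ids to leave out entirely.
#' @return list of chains; each chain is a list of slots. A slot is either
#'   `list(type = "contig", id, orient)` or `list(type = "bubble", a, b,
#'   orient_a, orient_b, origin, gap_in_a, gap_in_b, gap_out_a, gap_out_b)`;
#'   slots carry `gap_after` (bp to the next slot, NA at chain end or taken
#'   from the bubble edges at bubble boundaries).
#' @export
build_chains <- function(included, contigs, repeats = character()) {
  items <- included$items
  # link table: each item pairs up to two (node, port) couples; bubbles are
  # pseudo-nodes with ports "in" (c1 side) and "out" (c2 side)
  links <- list()
  bubbles <- list()
  for (i in seq_along(items)) {
    it <- items[[i]]
    if (it$type == "edge") {
      links[[length(links) + 1L]] <- list(
        a = it$c_a, pa = it$e_a, b = it$c_b, pb = it$e_b,
        gap_a = it$gap, gap_b = it$gap)
    } else {
      br <- it$bubble
      bid <- paste0(".bub", i)
      bubbles[[bid]] <- it
      links[[length(links) + 1L]] <- list(
        a = br$c1, pa = br$e1, b = bid, pb = "in",
        gap_a = mean(c(br$g_c1a, br$g_c1b), na.rm = TRUE),
        gap_b = NA_real_)
      if (!is.na(br$c2) && (br$w_ac2 > 0L || br$w_bc2 > 0L))
        links[[length(links) + 1L]] <- list(
          a = bid, pa = "out", b = br$c2, pb = br$e2,
          gap_a = mean(c(br$g_ac2, br$g_bc2), na.rm = TRUE),
          gap_b = NA_real_)
    }
  }
  port <- new.env(parent = emptyenv())   # "node:port" -> link index
  for (k in seq_along(links)) {
    l <- links[[k]]
    assign(paste0(l$a, ":", l$pa), k, envir = port)
    assign(paste0(l$b, ":", l$pb), k, envir = port)
  }
  node_ports <- function(n) {
    if (startsWith(n, ".bub")) c("in", "out") else c("5p", "3p")
  }
  nodes <- unique(c(setdiff(names(contigs), repeats), names(bubbles)))
  linked <- unique(unlist(lapply(links, function(l) c(l$a, l$b))))
  visited <- new.env(parent = emptyenv())
  # bubble heterotigs are emitted through their pseudo-node only
  for (it in bubbles) {
    visited[[it$bubble$a]] <- TRUE
    visited[[it$bubble$b]] <- TRUE
  }
  chains <- list()
  # deterministic order: real contigs lexicographically, then leftover cycles
  ordering <- c(sort(intersect(nodes, setdiff(nodes, names(bubbles)))),
                sort(names(bubbles)))
  for (start0 in ordering) {
    if (!is.null(visited[[start0]])) next
    if (!(start0 %in% linked)) {
      if (!startsWith(start0, ".bub")) {
        visited[[start0]] <- TRUE
        chains[[length(chains) + 1L]] <-
          list(list(type = "contig", id = start0, orient = "+",
                    gap_after = NA_real_))
      }
      next
    }
    # walk to a terminal (or back to start0 for a cycle)
    cur <- start0
    prev_link <- 0L
    repeat {
      ports <- node_ports(cur)
      free <- ports[vapply(ports, function(p)
        is.null(port[[paste0(cur, ":", p)]]), logical(1))]
      li <- NULL; lp <- NULL
      for (p in ports) {
        cand <- port[[paste0(cur, ":", p)]]
        if (!is.null(cand) && cand != prev_link) { li <- cand; lp <- p; break }
      }
      if (length(free) || is.null(li)) break
      l <- links[[li]]
      prev_link <- li
      nxtnode <- if (l$a == cur && l$pa == lp) l$b else l$a
      if (nxtnode == start0) { cur <- start0; break }
      cur <- nxtnode
    }
    term <- cur
    # choose entry port: the free port; in a cycle, break before start0's
    # first port
    ports <- node_ports(term)
    freep <- ports[vapply(ports, function(p)
      is.null(port[[paste0(term, ":", p)]]), logical(1))]
    entry <- if (length(freep)) freep[1] else ports[1]
    chain <- list()
    cur <- term; cur_entry <- entry; prev_link <- 0L
    repeat {
      visited[[cur]] <- TRUE
      exit <- setdiff(node_ports(cur), cur_entry)[1]
      li <- port[[paste0(cur, ":", exit)]]
      if (!is.null(li) && li == prev_link) li <- NULL   # safety
      gap_next <- NA_real_
      nxt <- NULL
      if (!is.null(li)) {
        l <- links[[li]]
        gap_next <- l$gap_a
        nxt <- if (l$a == cur && l$pa == exit) c(l$b, l$pb) else c(l$a, l$pa)
        if (!is.null(visited[[nxt[1]]])) nxt <- NULL   # cycle closes here
      }
      if (startsWith(cur, ".bub")) {
        it <- bubbles[[cur]]; br <- it$bubble
        fwd <- (cur_entry == "in")
        oa <- if (fwd) br$a_end1 else br$a_end2
        ob <- if (fwd) br$b_end1 else br$b_end2
        chain[[length(chain) + 1L]] <- list(
          type = "bubble", a = br$a, b = br$b,
          orient_a = if (oa == "5p") "+" else "-",
          orient_b = if (ob == "5p") "+" else "-",
          origin = it$origin,
          gap_in_a = if (fwd) br$g_c1a else br$g_ac2,
          gap_in_b = if (fwd) br$g_c1b else br$g_bc2,
          gap_out_a = if (fwd) br$g_ac2 else br$g_c1a,
          gap_out_b = if (fwd) br$g_bc2 else br$g_c1b,
          gap_after = gap_next)
      } else {
        chain[[length(chain) + 1L]] <- list(
          type = "contig", id = cur,
          orient = if (cur_entry == "5p") "+" else "-",
          gap_after = gap_next)
      }
      if (is.null(nxt)) break
      prev_link <- li
      cur <- nxt[1]; cur_entry <- nxt[2]
    }
    chains[[length(chains) + 1L]] <- chain
  }
  chains
}

#' Phase the bubbles of each chain into complementary groups
#'
#' Within a chain, heterotigs are two-coloured so that every bubble
#' contributes one heterotig to each colour. Read pairs whose two ends map
#' to heterotigs of different bubbles vote for placing those heterotigs in
#' the same group; colours are assigned greedily along the chain by majority
#' vote against the currently open group pair. A bubble with no linking
#' evidence (or an exact vote tie, which is also logged as a conflict)
#' starts a new complementary group pair.
#'
#' @param chains output of [build_chains()].
#' @param het_links data.frame of cross-bubble link counts: contig_a,
#'   contig_b, n_links (unordered heterotig pairs).
#' @return list: `groups` (data.frame: group, complement, chain, n_members),
#'   `members` (data.frame: group, contig), `assignment` (named vector
#'   contig -> group), `conflicts` (number of minority votes overridden).
#' @export
phase_chains <- function(chains, het_links = NULL) {
  lk <- new.env(parent = emptyenv())
  if (!is.null(het_links) && nrow(het_links)) {
    for (i in seq_len(nrow(het_links))) {
      k <- paste(min(het_links$contig_a[i], het_links$contig_b[i]),
                 max(het_links$contig_a[i], het_links$contig_b[i]))
      lk[[k]] <- (lk[[k]] %||% 0L) + het_links$n_links[i]
    }
  }
  votes <- function(x, grp) {
    if (!length(grp)) return(0)
    sum(vapply(grp, function(y)
      as.numeric(lk[[paste(min(x, y), max(x, y))]] %||% 0), numeric(1)))
  }
  groups <- list(); members <- list(); conflicts <- 0L
  gid <- 0L
  for (ci in seq_along(chains)) {
    side1 <- character(); side2 <- character()
    flush <- function() {
      if (!length(side1)) return()
      gid <<- gid + 1L; g1 <- sprintf("pg%04d", gid)
      gid <<- gid + 1L; g2 <- sprintf("pg%04d", gid)
      groups[[length(groups) + 1L]] <<- data.frame(
        group = c(g1, g2), complement = c(g2, g1), chain = ci,
        n_members = c(length(side1), length(side2)),
        stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <<- data.frame(
        group = c(rep(g1, length(side1)), rep(g2, length(side2))),
        contig = c(side1, side2), stringsAsFactors = FALSE)
      side1 <<- character(); side2 <<- character()
    }
    for (slot in chains[[ci]]) {
      if (slot$type != "bubble") next
      if (!length(side1)) { side1 <- slot$a; side2 <- slot$b; next }
      same <- votes(slot$a, side1) + votes(slot$b, side2)
      cross <- votes(slot$a, side2) + votes(slot$b, side1)
      if (same + cross == 0) { flush(); side1 <- slot$a; side2 <- slot$b }
      else if (same > cross) {
        side1 <- c(side1, slot$a); side2 <- c(side2, slot$b)
        conflicts <- conflicts + cross
      } else if (cross > same) {
        side1 <- c(side1, slot$b); side2 <- c(side2, slot$a)
        conflicts <- conflicts + same
      } else {
        conflicts <- conflicts + same
        flush(); side1 <- slot$a; side2 <- slot$b
      }
    }
    flush()
  }
  groups <- if (length(groups)) do.call(rbind, groups) else
    data.frame(group = character(), complement = character(),
               chain = integer(), n_members = integer())
  members <- if (length(members)) do.call(rbind, members) else
    data.frame(group = character(), contig = character())
  assignment <- stats::setNames(members$group, members$contig)
  list(groups = groups, members = members, assignment = assignment,
       conflicts = conflicts)
}

#' Emit the two linear haploid scaffolds per chain
#'
#' Haplotype 1 takes, in each bubble, the heterotig of the phase-group side
#' containing the lexicographically smallest member; haplotype 2 takes the
#' complement. Homotigs and singletons appear identically in both files.
#' Inter-contig gaps are rendered as N-runs of length
#' `max(round(gap), gap_floor)` (rounding half away from zero).
#'
#' @param chains output of [build_chains()].
#' @param phasing output of [phase_chains()].
#' @param contigs contig set.
#' @param gap_floor minimum emitted N-run (default 10).
#' @return list: `hap1`, `hap2` (named character vectors of scaffold
#'   sequences), `layout` (data.frame: scaffold, hap, position, contig,
#'   orient, gap_after).
#' @export
emit_haplotypes <- function(chains, phasing, contigs, gap_floor = 10L) {
  assignment <- phasing$assignment
  # group side -> haplotype tag: side holding the smallest member id is hap1
  side_tag <- character()
  if (nrow(phasing$groups)) {
    done <- character()
    for (i in seq_len(nrow(phasing$groups))) {
      g <- phasing$groups$group[i]
      if (g %in% done) next
      comp <- phasing$groups$complement[i]
      m1 <- phasing$members$contig[phasing$members$group == g]
      m2 <- phasing$members$contig[phasing$members$group == comp]
      if (min(m1) < min(m2)) { side_tag[g] <- "hap1"; side_tag[comp] <- "hap2" }
      else { side_tag[g] <- "hap2"; side_tag[comp] <- "hap1" }
      done <- c(done, g, comp)
    }
  }
  oriented <- function(id, orient) {
    s <- contigs[[id]]
    if (orient == "+") s else revcomp(s)
  }
  gap_n <- function(g) {
    if (is.na(g)) gap_floor else max(round_half_away(g), gap_floor)
  }
  # slot-boundary gap for one haplotype: bubble slots carry per-heterotig
  # edge gaps on each side; plain links carry one shared estimate
  boundary_gap <- function(left, right, a_is_1_left, a_is_1_right, hap) {
    if (!is.null(right) && right$type == "bubble") {
      g <- if ((hap == 1L) == a_is_1_right) right$gap_in_a else right$gap_in_b
      if (!is.na(g)) return(g)
    }
    if (left$type == "bubble") {
      g <- if ((hap == 1L) == a_is_1_left) left$gap_out_a else left$gap_out_b
      if (!is.na(g)) return(g)
    }
    left$gap_after
  }
  hap1 <- character(); hap2 <- character()
  layout <- list()
  for (ci in seq_along(chains)) {
    chain <- chains[[ci]]
    sid <- sprintf("scaffold%04d", ci)
    p1 <- character(); p2 <- character()
    a1 <- vapply(chain, function(s) {
      if (s$type != "bubble") return(TRUE)
      ga <- assignment[s$a]
      is.na(ga) || is.na(side_tag[ga]) || side_tag[ga] == "hap1"
    }, logical(1))
    for (k in seq_along(chain)) {
      slot <- chain[[k]]
      lastslot <- k == length(chain)
      nxt <- if (lastslot) NULL else chain[[k + 1L]]
      nxt_a1 <- if (lastslot) TRUE else a1[k + 1L]
      if (slot$type == "contig") {
        s <- oriented(slot$id, slot$orient)
        p1 <- c(p1, s); p2 <- c(p2, s)
        layout[[length(layout) + 1L]] <- data.frame(
          scaffold = sid, hap = "both", position = k, contig = slot$id,
          orient = slot$orient,
          gap_after = if (lastslot) NA_real_ else slot$gap_after)
      } else {
        ida <- if (a1[k]) slot$a else slot$b
        idb <- if (a1[k]) slot$b else slot$a
        ora <- if (a1[k]) slot$orient_a else slot$orient_b
        orb <- if (a1[k]) slot$orient_b else slot$orient_a
        p1 <- c(p1, oriented(ida, ora))
        p2 <- c(p2, oriented(idb, orb))
        layout[[length(layout) + 1L]] <- data.frame(
          scaffold = sid, hap = c("hap1", "hap2"), position = k,
          contig = c(ida, idb), orient = c(ora, orb),
          gap_after = if (lastslot) NA_real_ else slot$gap_after)
      }
      if (!lastslot) {
        p1 <- c(p1, strrep("N", gap_n(
          boundary_gap(slot, nxt, a1[k], nxt_a1, 1L))))
        p2 <- c(p2, strrep("N", gap_n(
          boundary_gap(slot, nxt, a1[k], nxt_a1, 2L))))
      }
    }
    hap1[sid] <- paste(p1, collapse = "")
    hap2[sid] <- paste(p2, collapse = "")
  }
  list(hap1 = hap1, hap2 = hap2,
       layout = do.call(rbind, layout) %||%
         data.frame(scaffold = character(), hap = character(),
                    position = integer(), contig = character(),
                    orient = character(), gap_after = numeric()))
}
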