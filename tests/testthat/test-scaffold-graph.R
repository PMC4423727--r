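# Scaffold-graph construction: pair orientation/gap inference, edge
# aggregation, minimum support, repeat flagging, and conservation.

ct2 <- c(c1 = strrep("A", 1000), c2 = strrep("C", 1000))

aln_row <- function(contig, start, end, strand) {
  list(contig = contig, start = start, end = end, strand = strand)
}

test_that("pair_to_edge nominates ends and estimates gaps from tails", {
  # forward hit 150 bp from c1's 3' terminus; reverse hit 150 bp into c2
  r1 <- aln_row("c1", 850L, 925L, "+")   # tail = 1000 - 850 = 150
  r2 <- aln_row("c2", 75L, 150L, "-")    # tail = end = 150
  e <- pair_to_edge(r1, r2, 400L, ct2)
  expect_identical(e$status, "LINK")
  expect_identical(e$end_a$contig, "c1"); expect_identical(e$end_a$end, "3p")
  expect_identical(e$end_b$contig, "c2"); expect_identical(e$end_b$end, "5p")
  expect_equal(e$gap, 100)

  # overlapping contigs: tails 250/250 give a negative gap
  r1 <- aln_row("c1", 750L, 825L, "+")
  r2 <- aln_row("c2", 175L, 250L, "-")
  expect_equal(pair_to_edge(r1, r2, 400L, ct2)$gap, -100)

  # both ends forward on one contig: invalid innie geometry
  r1 <- aln_row("c1", 100L, 175L, "+")
  r2 <- aln_row("c1", 400L, 475L, "+")
  expect_identical(pair_to_edge(r1, r2, 400L, ct2)$status, "REJECT")

  # proper innie on one contig reports the observed span
  r2 <- aln_row("c1", 275L, 350L, "-")
  e <- pair_to_edge(r1, r2, 400L, ct2)
  expect_identical(e$status, "SAME_CONTIG")
  expect_equal(e$span, 250)
})

make_aln <- function(rows) {
  dt <- data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(read_id = paste0(r$pair, "/", r$mate),
                           pair_id = r$pair, mate = r$mate, contig = r$contig,
                           start = r$start, end = r$end, strand = r$strand,
                           mult = r$mult %||% 1L)
  }))
  dt
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("build_scaffold_graph aggregates edges and averages gaps", {
  rows <- list(
    list(pair = "p1", mate = 1L, contig = "c1", start = 850L, end = 925L, strand = "+"),
    list(pair = "p1", mate = 2L, contig = "c2", start = 75L, end = 150L, strand = "-"),
    list(pair = "p2", mate = 1L, contig = "c1", start = 870L, end = 945L, strand = "+"),
    list(pair = "p2", mate = 2L, contig = "c2", start = 75L, end = 150L, strand = "-"))
  # p1 gap: 400-150-150 = 100; p2 gap: 400-130-150 = 120
  b <- build_scaffold_graph(make_aln(rows), ct2, 400L)
  expect_identical(nrow(b$graph$edges), 1L)
  expect_identical(b$graph$edges$weight, 2L)
  expect_equal(b$graph$edges$gap, 110)
  expect_true(all(b$pair_status$status == "LINK"))
})

test_that("edge identity includes end tags", {
  rows <- list(
    list(pair = "p1", mate = 1L, contig = "c1", start = 850L, end = 925L, strand = "+"),
    list(pair = "p1", mate = 2L, contig = "c2", start = 75L, end = 150L, strand = "-"),
    list(pair = "p2", mate = 1L, contig = "c1", start = 850L, end = 925L, strand = "+"),
    list(pair = "p2", mate = 2L, contig = "c2", start = 850L, end = 925L, strand = "+"))
  b <- build_scaffold_graph(make_aln(rows), ct2, 400L)
  expect_identical(nrow(b$graph$edges), 2L)
  expect_identical(b$graph$edges$weight, c(1L, 1L))
})

test_that("multi-mapped pairs are suppressed by default", {
  rows <- list(
    list(pair = "p1", mate = 1L, contig = "c1", start = 850L, end = 925L,
         strand = "+", mult = 3L),
    list(pair = "p1", mate = 2L, contig = "c2", start = 75L, end = 150L,
         strand = "-"))
  b <- build_scaffold_graph(make_aln(rows), ct2, 400L)
  expect_identical(nrow(b$graph$edges), 0L)
  expect_identical(b$pair_status$status, "MULTIPLY_MAPPED_SUPPRESSED")
  b2 <- build_scaffold_graph(make_aln(rows), ct2, 400L,
                             allow_multimapped = TRUE)
  expect_identical(nrow(b2$graph$edges), 1L)
})

test_that("graph build is invariant to mate-order swap", {
  u <- get_small_universe()
  a <- u$assignments[[1]]
  a <- a[!is.na(a$contig)]
  a$mult <- 1L
  b1 <- build_scaffold_graph(a, u$truth$contigs, 400L)
  swapped <- data.table::copy(a)
  swapped$mate <- ifelse(swapped$mate == 1L, 2L, 1L)
  b2 <- build_scaffold_graph(swapped, u$truth$contigs, 400L)
  expect_equal(as.data.frame(b1$graph$edges), as.data.frame(b2$graph$edges))
})

test_that("edge weights match a direct tally of pair_to_edge outcomes", {
  u <- get_small_universe()
  a <- u$assignments[[1]]
  a <- a[!is.na(a$contig)]
  a$mult <- 1L
  pairs <- unique(a$pair_id)[1:100]
  a <- a[a$pair_id %in% pairs]
  b <- build_scaffold_graph(a, u$truth$contigs, 400L)
  # oracle: loop pair_to_edge over each pair, tally LINK edges
  tally <- new.env(parent = emptyenv())
  for (p in pairs) {
    rows <- a[a$pair_id == p]
    if (nrow(rows) != 2L) next
    e <- pair_to_edge(rows[1, ], rows[2, ], 400L, u$truth$contigs)
    if (e$status != "LINK") next
    k <- paste(e$end_a$contig, e$end_a$end, e$end_b$contig, e$end_b$end)
    tally[[k]] <- (if (is.null(tally[[k]])) 0L else tally[[k]]) + 1L
  }
  ed <- b$graph$edges
  expect_identical(sum(ed$weight), sum(unlist(as.list(tally))))
  for (i in seq_len(nrow(ed))) {
    k1 <- paste(ed$c_a[i], ed$e_a[i], ed$c_b[i], ed$e_b[i])
    k2 <- paste(ed$c_b[i], ed$e_b[i], ed$c_a[i], ed$e_a[i])
    cnt <- max(tally[[k1]] %||% 0L, tally[[k2]] %||% 0L)
    expect_identical(ed$weight[i], cnt)
  }
})

test_that("weight conservation: edges + non-link statuses = input pairs", {
  u <- get_small_universe()
  a <- u$assignments[[1]]
  data.table::setDT(a)
  a_mapped <- a[!is.na(contig)]
  a_mapped[, mult := .N, by = read_id]
  all_ids <- unique(a$pair_id)
  # pairs with an unmapped end must still be reported: rebuild full table
  unmapped <- a[is.na(contig)]
  full <- rbind(a_mapped, unmapped, fill = TRUE)
  b <- build_scaffold_graph(full[!is.na(contig)], u$truth$contigs, 400L)
  ps <- b$pair_status
  # every pair with at least one mapped end gets exactly one record
  expect_identical(nrow(ps), length(unique(full[!is.na(contig)]$pair_id)))
  n_link_pairs <- sum(ps$status == "LINK")
  expect_identical(sum(b$graph$edges$weight), n_link_pairs)
  expect_identical(n_link_pairs + sum(ps$status != "LINK"), nrow(ps))
})

test_that("min support marks edges excluded but keeps them for rendering", {
  g <- scaffold_graph(
    data.frame(c_a = c("c1", "c1"), e_a = "3p", c_b = c("c2", "c3"),
               e_b = "5p", weight = c(1L, 2L)),
    c(c1 = 500L, c2 = 500L, c3 = 500L))
  expect_error(apply_min_support(g, 0), "min_support")
  g2 <- apply_min_support(g, 2)
  expect_identical(g2$edges$excluded, c(TRUE, FALSE))
  expect_identical(nrow(end_edges(g2, "c1", "3p")), 1L)
  g3 <- apply_min_support(g, 1)
  expect_false(any(g3$edges$excluded))
})

test_that("repeat flagging by degree and depth thresholds", {
  # hub contig with degree 12 against median degree 2
  edges <- rbind(
    data.frame(c_a = "hub", e_a = rep(c("5p", "3p"), 6),
               c_b = sprintf("x%02d", 1:12), e_b = "5p"),
    data.frame(c_a = sprintf("x%02d", 1:11), e_a = "3p",
               c_b = sprintf("x%02d", 2:12), e_b = "3p"))
  lens <- stats::setNames(rep(500L, 13), c("hub", sprintf("x%02d", 1:12)))
  g <- scaffold_graph(edges, lens)
  g <- flag_repeats(g, degree_factor = 3)
  expect_identical(g$repeats, "hub")

  # quiet graph: nothing flagged
  g2 <- scaffold_graph(
    data.frame(c_a = "c1", e_a = "3p", c_b = "c2", e_b = "5p"),
    c(c1 = 500L, c2 = 500L))
  expect_identical(flag_repeats(g2)$repeats, character())

  # depth rule: 240 with modal depth 80 and factor 2
  depths <- c(stats::setNames(rep(80, 10), sprintf("x%02d", 1:10)),
              hub = 240)
  g3 <- flag_repeats(g2, depths = depths[names(depths) %in% c("hub")],
                     depth_factor = 2)
  depths_all <- c(c1 = 80, c2 = 80, hub = 240)
  g4 <- scaffold_graph(
    data.frame(c_a = "c1", e_a = "3p", c_b = "c2", e_b = "5p"),
    c(c1 = 500L, c2 = 500L, hub = 500L))
  g4 <- flag_repeats(g4, depths = depths_all, depth_factor = 2)
  expect_identical(g4$repeats, "hub")
})

test_that("gap estimates recover the true gap exactly in the error-free regime", {
  # construct pairs spanning a known 120-bp gap with exact inserts
  rows <- list()
  for (i in 1:20) {
    t1 <- 80L + i   # tail on c1
    t2 <- 400L - 120L - t1
    rows[[length(rows) + 1L]] <-
      list(pair = paste0("g", i), mate = 1L, contig = "c1",
           start = 1000L - t1, end = 1000L - t1 + 75L, strand = "+")
    rows[[length(rows) + 1L]] <-
      list(pair = paste0("g", i), mate = 2L, contig = "c2",
           start = t2 - 75L, end = t2, strand = "-")
  }
  b <- build_scaffold_graph(make_aln(rows), ct2, 400L)
  expect_identical(nrow(b$graph$edges), 1L)
  expect_equal(b$graph$edges$gap, 120)

  # with insert jitter the estimate tightens as support grows
  set.seed(9)
  est_err <- function(n) {
    rows <- list()
    for (i in seq_len(n)) {
      ins <- round(stats::rnorm(1, 400, 30))
      t1 <- 100L
      t2 <- as.integer(ins) - 120L - t1
      rows[[length(rows) + 1L]] <-
        list(pair = paste0("j", i), mate = 1L, contig = "c1",
             start = 900L, end = 975L, strand = "+")
      rows[[length(rows) + 1L]] <-
        list(pair = paste0("j", i), mate = 2L, contig = "c2",
             start = t2 - 75L, end = t2, strand = "-")
    }
    abs(build_scaffold_graph(make_aln(rows), ct2, 400L)$graph$edges$gap - 120)
  }
  err_small <- mean(replicate(12, est_err(4)))
  err_large <- mean(replicate(12, est_err(64)))
  expect_lt(err_large, err_small)
})
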