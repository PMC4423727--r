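# Bubble acceptance, greedy linking, chain construction, phasing, and
# haploid emission.

perfect_row <- function(c1, a, b, c2, e1 = "3p", e2 = "5p",
                        w = c(5L, 5L, 5L, 5L), g = c(50, 50, 50, 50)) {
  data.frame(c1 = c1, a = a, b = b, c2 = c2, e1 = e1, e2 = e2,
             a_end1 = "5p", a_end2 = "3p", b_end1 = "5p", b_end2 = "3p",
             w_c1a = w[1], w_c1b = w[2], w_ac2 = w[3], w_bc2 = w[4],
             g_c1a = g[1], g_c1b = g[2], g_ac2 = g[3], g_bc2 = g[4],
             stringsAsFactors = FALSE)
}

test_that("imperfect bubbles are accepted under the occupancy rule", {
  pb <- perfect_row("c1", "a1", "b1", "c2")
  # two imperfect candidates sharing heterotig x1 on the same end
  imp <- rbind(
    cbind(perfect_row("c3", "x1", "y1", "c4"),
          missing_edges = 0L, conflict_count = 1L, total_support = 20L),
    cbind(perfect_row("c5", "x1", "y2", "c6"),
          missing_edges = 0L, conflict_count = 2L, total_support = 10L))
  acc <- accept_bubbles(pb, imp)
  expect_identical(nrow(acc$accepted), 2L)
  expect_identical(acc$accepted$a, c("a1", "x1"))
  expect_identical(acc$accepted$b[2], "y1")   # higher perfectness wins

  # reusing an edge already included by a perfect bubble is disallowed
  imp2 <- cbind(perfect_row("c1", "a1", "z9", "c7"),
                missing_edges = 1L, conflict_count = 0L, total_support = 9L)
  acc2 <- accept_bubbles(pb, imp2)
  expect_identical(nrow(acc2$accepted), 1L)

  # a disjoint positive candidate is accepted
  imp3 <- cbind(perfect_row("c8", "m1", "n1", "c9"),
                missing_edges = 1L, conflict_count = 0L, total_support = 9L)
  acc3 <- accept_bubbles(pb, imp3)
  expect_identical(nrow(acc3$accepted), 2L)
})

test_that("greedy linking prefers weight, breaks ties lexicographically, and
           respects occupancy and repeat flags", {
  lens <- c(c = 400L, d = 400L, e = 400L, f = 400L, rep1 = 400L)
  g <- scaffold_graph(data.frame(
    c_a = c("c", "c", "c", "e"), e_a = c("3p", "3p", "5p", "3p"),
    c_b = c("d", "e", "f", "rep1"), e_b = c("5p", "5p", "5p", "5p"),
    weight = c(10L, 7L, 8L, 9L), gap = 0), lens)
  g$repeats <- "rep1"
  inc <- greedy_link(g, new_included_set())
  picked <- vapply(inc$items, function(it) paste(it$c_a, it$c_b), "")
  expect_true("c d" %in% picked)                    # weight 10 beats 7
  expect_false("c e" %in% picked)                   # c:3p already used
  expect_true("c f" %in% picked)                    # other end still free
  expect_false(any(grepl("rep1", picked)))          # repeats never linked
  # occupancy: every end key appears once
  expect_identical(anyDuplicated(names(inc$occ)), 0L)

  # ties break toward the lexicographically smaller partner
  g2 <- scaffold_graph(data.frame(
    c_a = c("c", "c"), e_a = "3p", c_b = c("e", "d"), e_b = "5p",
    weight = 8L, gap = 0), lens[1:4])
  inc2 <- greedy_link(g2, new_included_set())
  picked2 <- vapply(inc2$items, function(it) paste(it$c_a, it$c_b), "")
  expect_identical(picked2, "c d")
})

test_that("chains alternate contigs and bubbles with consistent orientation", {
  contigs <- c(c1 = random_seq(1000), a1 = random_seq(300),
               b1 = random_seq(300), c2 = random_seq(1000),
               s1 = random_seq(120))
  pb <- perfect_row("c1", "a1", "b1", "c2")
  acc <- accept_bubbles(pb)
  ch <- build_chains(acc$included, contigs)
  expect_length(ch, 2L)   # the bubble chain and the singleton
  main <- ch[[which(vapply(ch, length, 0L) == 3L)]]
  types <- vapply(main, `[[`, "", "type")
  expect_identical(types, c("contig", "bubble", "contig"))
  expect_setequal(c(main[[1]]$id, main[[3]]$id), c("c1", "c2"))
  single <- ch[[which(vapply(ch, length, 0L) == 1L)]]
  expect_identical(single[[1]]$id, "s1")
})

test_that("phasing follows majority votes and starts new groups without
           evidence", {
  contigs <- c(c1 = random_seq(400), a1 = random_seq(300),
               b1 = random_seq(300), c2 = random_seq(400),
               a2 = random_seq(300), b2 = random_seq(300),
               c3 = random_seq(400))
  pb <- rbind(perfect_row("c1", "a1", "b1", "c2"),
              perfect_row("c2", "a2", "b2", "c3"))
  acc <- accept_bubbles(pb)
  ch <- build_chains(acc$included, contigs)

  # clear evidence: 5 links a1-a2, none crossing
  ph <- phase_chains(ch, data.frame(contig_a = "a1", contig_b = "a2",
                                    n_links = 5L))
  grp <- split(ph$members$contig, ph$members$group)
  expect_identical(length(grp), 2L)
  expect_true(any(vapply(grp, function(g) setequal(g, c("a1", "a2")),
                         TRUE)))
  expect_identical(ph$conflicts, 0)

  # no evidence at all: each bubble makes its own complementary pair
  ph0 <- phase_chains(ch, NULL)
  expect_identical(nrow(ph0$groups), 4L)

  # conflicting evidence: majority wins, minority logged
  ph2 <- phase_chains(ch, data.frame(
    contig_a = c("a1", "a1"), contig_b = c("a2", "b2"),
    n_links = c(3L, 1L)))
  grp2 <- split(ph2$members$contig, ph2$members$group)
  expect_true(any(vapply(grp2, function(g) setequal(g, c("a1", "a2")),
                         TRUE)))
  expect_identical(ph2$conflicts, 1)
})

test_that("complementary groups partition every bubble's heterotigs", {
  contigs <- c(c1 = random_seq(400), a1 = random_seq(300),
               b1 = random_seq(300), c2 = random_seq(400),
               a2 = random_seq(300), b2 = random_seq(300),
               c3 = random_seq(400))
  pb <- rbind(perfect_row("c1", "a1", "b1", "c2"),
              perfect_row("c2", "a2", "b2", "c3"))
  acc <- accept_bubbles(pb)
  ch <- build_chains(acc$included, contigs)
  ph <- phase_chains(ch, data.frame(contig_a = "a1", contig_b = "a2",
                                    n_links = 4L))
  comp <- stats::setNames(ph$groups$complement, ph$groups$group)
  for (i in seq_len(nrow(pb))) {
    ga <- ph$assignment[pb$a[i]]; gb <- ph$assignment[pb$b[i]]
    expect_false(is.na(ga) || is.na(gb))
    expect_identical(unname(comp[ga]), unname(gb))
  }
})

test_that("haploid emission obeys the length arithmetic and gap floor", {
  contigs <- c(c1 = random_seq(1000), a1 = random_seq(300),
               b1 = random_seq(300), c2 = random_seq(1000))
  pb <- perfect_row("c1", "a1", "b1", "c2", g = c(50, 50, 50, 50))
  acc <- accept_bubbles(pb)
  ch <- build_chains(acc$included, contigs)
  ph <- phase_chains(ch, NULL)
  out <- emit_haplotypes(ch, ph, contigs, gap_floor = 10L)
  expect_length(out$hap1, 1L)
  expect_identical(nchar(out$hap1[[1]]), 1000L + 50L + 300L + 50L + 1000L)
  expect_identical(nchar(out$hap2[[1]]), nchar(out$hap1[[1]]))
  expect_false(identical(out$hap1[[1]], out$hap2[[1]]))
  # smaller heterotig id lands in hap1
  expect_true(grepl(contigs[["a1"]], out$hap1[[1]], fixed = TRUE) ||
                grepl(revcomp(contigs[["a1"]]), out$hap1[[1]], fixed = TRUE))

  # negative gap estimates floor at gap_floor Ns
  pb2 <- perfect_row("c1", "a1", "b1", "c2", g = c(-30, -30, -30, -30))
  acc2 <- accept_bubbles(pb2)
  ch2 <- build_chains(acc2$included, contigs)
  out2 <- emit_haplotypes(ch2, phase_chains(ch2, NULL), contigs,
                          gap_floor = 10L)
  expect_identical(nchar(out2$hap1[[1]]), 1000L + 10L + 300L + 10L + 1000L)
})

test_that("singletons appear identically in both haplotype outputs", {
  contigs <- c(s1 = random_seq(500), s2 = random_seq(200))
  ch <- build_chains(new_included_set(), contigs)
  out <- emit_haplotypes(ch, phase_chains(ch, NULL), contigs)
  expect_identical(unname(out$hap1), unname(out$hap2))
  expect_identical(sort(unname(nchar(out$hap1))), c(200L, 500L))
})

test_that("orientation is applied by reverse complement in emission", {
  contigs <- c(p = random_seq(300), q = random_seq(200))
  inc <- greedy_link(scaffold_graph(
    data.frame(c_a = "p", e_a = "3p", c_b = "q", e_b = "3p",
               weight = 5L, gap = 20), nchar(contigs)),
    new_included_set())
  ch <- build_chains(inc, contigs)
  out <- emit_haplotypes(ch, phase_chains(ch, NULL), contigs)
  s <- out$hap1[[1]]
  # q is entered through its 3' end: reverse-complemented downstream of p
  expect_identical(nchar(s), 300L + 20L + 200L)
  expect_identical(substr(s, 1, 300), unname(contigs["p"]))
  expect_identical(substr(s, 321, 520), revcomp(unname(contigs["q"])))
})
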