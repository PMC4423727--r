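# Synthetic diploid universe: genome generation, read simulation, truth
# contigs, read assignment and alignment emission.

test_that("zero heterozygosity gives identical haplotypes", {
  g <- generate_diploid(2000, het_rate = 0, seed = 1)
  expect_identical(g$hap_a, g$hap_b)
  expect_identical(nrow(g$variants), 0L)
})

test_that("uniform variant counts satisfy the binomial bound", {
  g <- generate_diploid(100000, het_rate = 0.04, indel_fraction = 0,
                        seed = 2, placement = "uniform")
  n <- nrow(g$variants)
  expect_lt(abs(n - 4000), 3 * sqrt(100000 * 0.04 * 0.96))
  expect_true(all(g$variants$type == "SNP"))
  # hap B differs from hap A exactly at the variant positions
  av <- strsplit(g$hap_a, "")[[1]]
  bv <- strsplit(g$hap_b, "")[[1]]
  expect_identical(which(av != bv), g$variants$pos)
})

test_that("genome generation is deterministic and validates parameters", {
  g1 <- generate_diploid(5000, seed = 7)
  g2 <- generate_diploid(5000, seed = 7)
  expect_identical(g1$hap_b, g2$hap_b)
  expect_identical(g1$variants, g2$variants)
  expect_error(generate_diploid(100), "length")
  expect_error(generate_diploid(5000, het_rate = 0.7), "het_rate")
  expect_error(generate_diploid(5000, indel_fraction = 0.9),
               "indel_fraction")
})

test_that("hap B is exactly reconstructable from hap A plus variants", {
  g <- generate_diploid(20000, het_rate = 0.03, indel_fraction = 0.3,
                        seed = 9)
  v <- g$variants
  # independent reconstruction: walk hap A, substituting alt pieces
  pieces <- character()
  cur <- 1L
  for (i in seq_len(nrow(v))) {
    pieces <- c(pieces, substring(g$hap_a, cur, v$pos[i] - 1L))
    ref_end <- v$foot_end_a[i]
    seg <- substring(g$hap_a, v$pos[i], ref_end)
    alt <- switch(v$type[i],
      SNP = {
        bpos <- v$pos_b[i]
        substring(g$hap_b, bpos, bpos)
      },
      INS = substring(g$hap_b, v$pos_b[i], v$foot_end_b[i]),
      DEL = substring(g$hap_b, v$pos_b[i], v$pos_b[i]))
    pieces <- c(pieces, alt)
    cur <- ref_end + 1L
  }
  pieces <- c(pieces, substring(g$hap_a, cur, nchar(g$hap_a)))
  expect_identical(paste(pieces, collapse = ""), g$hap_b)
  expect_identical(nchar(g$hap_b), nchar(g$hap_a) + sum(v$len_change))
})

test_that("blocks placement clusters variants but keeps the overall rate", {
  g <- generate_diploid(300000, het_rate = 0.04, indel_fraction = 0,
                        seed = 4, placement = "blocks")
  rate <- nrow(g$variants) / 300000
  expect_gt(rate, 0.025); expect_lt(rate, 0.055)
  # clustered: many more long homozygous runs than uniform placement expects
  gaps <- diff(g$variants$pos)
  expect_gt(sum(gaps >= 150), 200)
})

test_that("read simulation hits target coverage with exact-insert option", {
  g <- generate_diploid(50000, het_rate = 0.01, seed = 5)
  rd <- simulate_paired_reads(g, coverage = 10, insert_mean = 400,
                              insert_sd = 0, seed = 6)
  total_bases <- nrow(rd) * 2 * 75
  expect_lt(abs(total_bases - 10 * (nchar(g$hap_a) + nchar(g$hap_b))),
            0.01 * 10 * 2 * 50000)
  expect_true(all(rd$insert == 400L))
  expect_error(simulate_paired_reads(g, insert_mean = 100), "insert_mean")
})

test_that("simulated reads are error-free substrings with innie geometry", {
  g <- generate_diploid(20000, het_rate = 0.02, seed = 8)
  rd <- simulate_paired_reads(g, coverage = 2, seed = 8)
  sq <- sim_read_seqs(g, rd)
  m <- dipscaffold:::expand_mates(rd)
  hap <- c(A = g$hap_a, B = g$hap_b)
  fwd <- m[m$strand == "+", ]
  idx <- match(fwd$read_id, sq$read_id)
  expect_identical(sq$seq[idx][1:50],
                   unname(substring(hap[fwd$hap], fwd$s, fwd$e)[1:50]))
  rev <- m[m$strand == "-", ]
  idx2 <- match(rev$read_id, sq$read_id)[1:50]
  expect_identical(sq$seq[idx2],
                   revcomp(substring(hap[rev$hap], rev$s, rev$e)[1:50]))
})

test_that("truth contigs realise the documented block geometry", {
  # no variants: a single genome-spanning homotig
  g0 <- generate_diploid(5000, het_rate = 0, seed = 1)
  t0 <- simulate_truth_contigs(g0)
  expect_identical(t0$table$class, "HOMOTIG")
  expect_identical(t0$table$end_a, 5000L)

  # one SNP at position 5000 in a 10-kb genome: heterotig pair of length
  # 149 flanked by two homotigs
  base <- random_seq(10000)
  gv <- generate_diploid(hap_a = base, het_rate = 0, seed = 1)
  gv$variants <- data.frame(pos = 5000L, type = "SNP", len_change = 0L,
                            pos_b = 5000L, foot_end_a = 5000L,
                            foot_end_b = 5000L)
  bb <- strsplit(base, "")[[1]]
  bb[5000] <- setdiff(c("A", "C", "G", "T"), bb[5000])[1]
  gv$hap_b <- paste(bb, collapse = "")
  t1 <- simulate_truth_contigs(gv, pad = 74)
  tab <- t1$table
  expect_identical(sum(tab$class == "HOMOTIG"), 2L)
  expect_identical(sum(tab$class == "HETEROTIG"), 2L)
  het <- tab[tab$class == "HETEROTIG" & tab$source == "A", ]
  expect_identical(het$end_a - het$start_a + 1L, 149L)
  expect_identical(tab$partner[tab$id == het$id], het$partner)

  # two SNPs 50 bp apart merge into a single heterotig pair
  gv$variants <- data.frame(pos = c(5000L, 5050L), type = "SNP",
                            len_change = 0L, pos_b = c(5000L, 5050L),
                            foot_end_a = c(5000L, 5050L),
                            foot_end_b = c(5000L, 5050L))
  t2 <- simulate_truth_contigs(gv, pad = 74)
  expect_identical(sum(t2$table$class == "HETEROTIG"), 2L)
  expect_error(simulate_truth_contigs(gv, pad = 74, min_homozygous_run = 100),
               "min_homozygous_run")
})

test_that("heterotig count equals the independent block computation", {
  g <- generate_diploid(200000, seed = 13, placement = "blocks")
  tr <- simulate_truth_contigs(g, pad = 74, min_homozygous_run = 150)
  v <- g$variants
  run <- v$pos[-1] - v$foot_end_a[-nrow(v)] - 1L
  n_blocks <- 1L + sum(run >= 150L)
  expect_identical(sum(tr$table$class == "HETEROTIG"), 2L * n_blocks)
})

test_that("read-contig assignment respects provenance and boundaries", {
  u <- get_small_universe()
  tab <- u$truth$table
  asn <- data.table::rbindlist(u$assignments)
  placed <- asn[!is.na(asn$contig), ]
  cls <- stats::setNames(tab$class, tab$id)
  src <- stats::setNames(tab$source, tab$id)
  het <- placed[cls[placed$contig] == "HETEROTIG", ]
  # heterotig members all share the contig's haplotype
  expect_true(all(het$hap == src[het$contig]))
  # homotig members include both origins for every decently covered homotig
  hom <- placed[cls[placed$contig] == "HOMOTIG", ]
  mix <- tapply(hom$hap, hom$contig, function(h) length(unique(h)))
  lens <- nchar(u$truth$contigs)
  expect_true(all(mix[lens[names(mix)] >= 200] == 2L))
})

test_that("emitted SAM decodes to exact read sequences (lossless lift-over)", {
  g <- generate_diploid(30000, seed = 17, placement = "blocks")
  tr <- simulate_truth_contigs(g)
  rd <- simulate_paired_reads(g, coverage = 4, seed = 18)
  asn <- assign_reads_to_contigs(tr, g, rd)
  f <- withr::local_tempfile(fileext = ".sam")
  emit_alignments(asn, tr, f, "sam", genome = g, reads = rd)
  aln <- read_alignments(f, "sam", tr$contigs)
  sq <- sim_read_seqs(g, rd)
  seqs <- stats::setNames(sq$seq, sq$read_id)
  n <- min(nrow(aln), 200L)
  for (i in seq_len(n)) {
    sub <- substring(tr$contigs[[aln$contig[i]]], aln$start[i] + 1L,
                     aln$end[i])
    want <- if (aln$strand[i] == "-") revcomp(sub) else sub
    expect_identical(unname(seqs[aln$read_id[i]]), want)
  }
})

test_that("boundary-spanning reads are emitted unmapped", {
  g <- generate_diploid(30000, seed = 19, placement = "blocks")
  tr <- simulate_truth_contigs(g)
  rd <- simulate_paired_reads(g, coverage = 4, seed = 20)
  asn <- assign_reads_to_contigs(tr, g, rd)
  expect_true(any(asn$reason != "mapped"))
  f <- withr::local_tempfile(fileext = ".sam")
  emit_alignments(asn, tr, f, "sam")
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "@")]
  flags <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 2L))
  expect_identical(sum(bitwAnd(flags, 4L) > 0L),
                   sum(asn$reason != "mapped"))
})
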