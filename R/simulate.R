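# Synthetic diploid benchmark universe: a two-haplotype genome with known
# variants, error-free paired reads with haplotype provenance, and a
# stringent-assembly contig set (homotigs from homozygous runs, heterotig
# pairs from merged heterozygous blocks) with full truth labels. Every
# downstream stage and all four quality metrics can run against it with no
# external data.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a diploid genome
#'
#' Haplotype A is seeded random DNA (or user-supplied); haplotype B is
#' derived by placing variant sites uniformly at rate `het_rate`. Each site
#' becomes a small indel (1-5 bp, insertion or deletion with equal
#' probability) with probability `indel_fraction`, otherwise a SNP to a
#' uniformly chosen different base. Deletions are truncated so variant
#' footprints never collide (a deletion squeezed to zero length falls back
#' to a SNP).
#'
#' @param length genome length (>= 1000) when hap_a is generated.
#' @param het_rate per-base heterozygosity rate in [0, 0.5).
#' @param indel_fraction fraction of variant sites realised as indels.
#' @param seed RNG seed.
#' @param hap_a optional haplotype-A sequence (overrides `length`).
#' @param placement "uniform": variant sites drawn uniformly over the genome;
#'   "blocks": clustered heterozygosity -- alternating homozygous runs
#'   (exponential, mean `run_mean`) and heterozygous blocks carrying variants
#'   at per-base rate `within_rate`, with block lengths chosen so the overall
#'   rate is still `het_rate`. Real diploid heterozygosity is clustered;
#'   the blocks mode reproduces the interleaved homozygous/heterozygous
#'   landscape a stringent assembler turns into homotigs and heterotig pairs.
#' @param within_rate per-base variant rate inside heterozygous blocks
#'   (blocks placement; must exceed `het_rate`).
#' @param run_mean mean homozygous run length in bp (blocks placement).
#' @return an object of class `diploid_genome`: hap_a, hap_b, variants
#'   (data.frame: pos, type, len_change, pos_b, foot_end_a, foot_end_b),
#'   het_rate, seed.
#' @export
generate_diploid <- function(length = 1e5, het_rate = 0.04,
                             indel_fraction = 0.1, seed = 1, hap_a = NULL,
                             placement = c("uniform", "blocks"),
                             within_rate = 0.1, run_mean = 400) {
  placement <- match.arg(placement)
  if (is.null(hap_a)) {
    if (length < 1000) stop("length must be >= 1000")
  } else length <- nchar(hap_a)
  if (het_rate < 0 || het_rate >= 0.5) stop("het_rate must be in [0, 0.5)")
  if (indel_fraction < 0 || indel_fraction > 0.5)
    stop("indel_fraction must be in [0, 0.5]")
  if (placement == "blocks" && within_rate <= het_rate)
    stop("within_rate must exceed het_rate for blocks placement")
  with_seed(seed, {
    if (is.null(hap_a)) hap_a <- random_dna(length)
    L <- nchar(hap_a)
    if (placement == "uniform") {
      n_var <- stats::rbinom(1L, L, het_rate)
      pos <- sort(sample.int(L, n_var))
    } else {
      block_mean <- run_mean * het_rate / (within_rate - het_rate)
      pos <- integer(0)
      cur <- 1L
      repeat {
        cur <- cur + max(1L, round(stats::rexp(1L, 1 / run_mean)))
        if (cur > L) break
        blen <- max(1L, round(stats::rexp(1L, 1 / block_mean)))
        hi <- min(L, cur + blen - 1L)
        hit <- which(stats::runif(hi - cur + 1L) < within_rate)
        pos <- c(pos, cur + hit - 1L)
        cur <- hi + 1L
        if (cur > L) break
      }
      pos <- unique(pos)
    }
    pos <- as.integer(pos)
    n_var <- length(pos)
    type <- ifelse(stats::runif(n_var) < indel_fraction,
                   ifelse(stats::runif(n_var) < 0.5, "INS", "DEL"), "SNP")
    ilen <- sample(1:5, n_var, replace = TRUE)
    gap_next <- c(diff(pos), L - pos[length(pos)] + 1L)
    if (!n_var) gap_next <- integer()
    dlen <- pmin(ilen, gap_next - 1L)
    type[type == "DEL" & dlen <= 0L] <- "SNP"
    len_change <- integer(n_var)
    len_change[type == "INS"] <- ilen[type == "INS"]
    len_change[type == "DEL"] <- -dlen[type == "DEL"]
    base_at <- function(p) substring(hap_a, p, p)
    alt_piece <- character(n_var)
    for (k in seq_len(n_var)) {   # n_var small relative to L; loop is fine
      p <- pos[k]
      if (type[k] == "SNP") {
        alt_piece[k] <- sample(setdiff(c("A", "C", "G", "T"), base_at(p)), 1L)
      } else if (type[k] == "INS") {
        alt_piece[k] <- paste0(base_at(p), random_dna(len_change[k]))
      } else {
        alt_piece[k] <- base_at(p)
      }
    }
    foot_end_a <- pos
    foot_end_a[type == "DEL"] <- pos[type == "DEL"] - len_change[type == "DEL"]
    # assemble hap B: reference pieces between variant footprints + alt pieces
    ref_start <- c(1L, foot_end_a + 1L)
    ref_end <- c(pos - 1L, nchar(hap_a))
    pieces <- character(2L * n_var + 1L)
    pieces[seq(1L, 2L * n_var + 1L, by = 2L)] <-
      substring(hap_a, ref_start, pmax(ref_end, ref_start - 1L))
    if (n_var) pieces[seq(2L, 2L * n_var, by = 2L)] <- alt_piece
    hap_b <- paste(pieces, collapse = "")
    off_before <- c(0L, cumsum(len_change))[seq_len(max(n_var, 1L))]
    if (!n_var) off_before <- integer()
    pos_b <- pos + off_before
    foot_end_b <- pos_b
    foot_end_b[type == "INS"] <- pos_b[type == "INS"] + ilen[type == "INS"]
    foot_end_b[type == "DEL"] <- pos_b[type == "DEL"] + 1L
    variants <- data.frame(pos = pos, type = type, len_change = len_change,
                           pos_b = pos_b, foot_end_a = foot_end_a,
                           foot_end_b = foot_end_b,
                           stringsAsFactors = FALSE)
    structure(list(hap_a = hap_a, hap_b = hap_b, variants = variants,
                   het_rate = het_rate, indel_fraction = indel_fraction,
                   seed = seed),
              class = "diploid_genome")
  })
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat("diploid genome: hap A", nchar(x$hap_a), "bp, hap B", nchar(x$hap_b),
      "bp,", nrow(x$variants), "variant sites (target het rate",
      x$het_rate, ")\n")
  invisible(x)
}

#' Simulate error-free paired reads from both haplotypes
#'
#' Fragments are drawn uniformly from each haplotype until the requested
#' per-haplotype fold coverage is reached; reads are the two fragment ends in
#' innie orientation (mate 1 forward at the fragment start, mate 2
#' reverse-complemented at the fragment end). Insert sizes are rounded
#' normal draws clamped to [2 x read_len, 2 x insert_mean].
#'
#' @param genome a `diploid_genome`.
#' @param read_len read length (bp, default 75).
#' @param insert_mean,insert_sd insert-size distribution (default sd =
#'   insert_mean / 10).
#' @param coverage per-haplotype fold coverage (default 40).
#' @param seed RNG seed.
#' @param library library name used in read ids.
#' @return a data.table of fragments, class `sim_reads`: pair_id, hap
#'   ("A"/"B"), frag_start (1-based on the origin haplotype), insert;
#'   attributes read_len, insert_mean, library.
#' @export
simulate_paired_reads <- function(genome, read_len = 75L, insert_mean = 400L,
                                  insert_sd = insert_mean / 10, coverage = 40,
                                  seed = 1, library = "lib") {
  stopifnot(inherits(genome, "diploid_genome"))
  if (insert_mean < 2L * read_len) stop("insert_mean must be >= 2 x read_len")
  frags <- with_seed(seed, {
    out <- lapply(c(A = "A", B = "B"), function(h) {
      L <- nchar(if (h == "A") genome$hap_a else genome$hap_b)
      n <- round(coverage * L / (2 * read_len))
      ins <- as.integer(round_half_away(stats::rnorm(n, insert_mean, insert_sd)))
      ins <- pmax(2L * read_len, pmin(2L * insert_mean, ins))
      ins <- pmin(ins, L)
      data.table::data.table(
        hap = h,
        frag_start = 1L + as.integer(floor(stats::runif(n) * (L - ins + 1L))),
        insert = ins)
    })
    data.table::rbindlist(out)
  })
  frags[, pair_id := sprintf("%s_%s_%07d", library, hap, seq_len(.N))]
  data.table::setattr(frags, "read_len", as.integer(read_len))
  data.table::setattr(frags, "insert_mean", as.integer(insert_mean))
  data.table::setattr(frags, "library", library)
  data.table::setattr(frags, "class", c("sim_reads", class(frags)))
  frags[]
}

# expand fragments to one row per read end (1-based inclusive intervals on
# the origin haplotype)
expand_mates <- function(reads) {
  rl <- attr(reads, "read_len")
  m1 <- data.table::data.table(
    pair_id = reads$pair_id, mate = 1L, hap = reads$hap,
    s = reads$frag_start, e = reads$frag_start + rl - 1L, strand = "+")
  m2 <- data.table::data.table(
    pair_id = reads$pair_id, mate = 2L, hap = reads$hap,
    s = reads$frag_start + reads$insert - rl,
    e = reads$frag_start + reads$insert - 1L, strand = "-")
  out <- data.table::rbindlist(list(m1, m2))
  out[, read_id := paste0(pair_id, "/", mate)]
  data.table::setorder(out, pair_id, mate)
  out[]
}

#' Read sequences for simulated reads
#'
#' Error-free by construction: each read equals its origin-haplotype
#' substring (reverse-complemented for the reverse mate).
#'
#' @param genome a `diploid_genome`.
#' @param reads a `sim_reads` table.
#' @return data.table: read_id, hap, mate, seq.
#' @export
sim_read_seqs <- function(genome, reads) {
  m <- expand_mates(reads)
  hapseq <- c(A = genome$hap_a, B = genome$hap_b)
  s <- substring(hapseq[m$hap], m$s, m$e)
  rev <- m$strand == "-"
  if (any(rev))
    s[rev] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(s[rev])))
  data.table::data.table(read_id = m$read_id, hap = m$hap, mate = m$mate,
                         seq = s)
}

#' Derive the stringent-assembly truth contig set
#'
#' Each variant is padded by `pad` bases on both sides; padded blocks whose
#' intervening homozygous run is shorter than `min_homozygous_run` merge into
#' one heterozygous block, realised as a heterotig pair (one contig per
#' haplotype, mutual partners). Each remaining homozygous run becomes a
#' homotig spanning the full run, so a homotig shares up to `pad` bases of
#' flanking sequence with each neighbouring heterotig -- as stringent
#' assembly of both haplotypes produces. Homozygous runs at the genome edges
#' shorter than `min_homozygous_run` are left unassembled.
#'
#' @param genome a `diploid_genome`.
#' @param pad bases of shared context a haplotype contig extends beyond its
#'   outermost variant (default 74 = read length - 1).
#' @param min_homozygous_run minimum homozygous run realised as a homotig;
#'   must exceed 2 x pad.
#' @return object of class `truth_contigs`: `contigs` (named sequences),
#'   `table` (data.frame: id, class HOMOTIG/HETEROTIG, source A/B/BOTH,
#'   start_a, end_a, start_b, end_b, partner), and the generation parameters.
#' @export
simulate_truth_contigs <- function(genome, pad = 74L,
                                   min_homozygous_run = 150L) {
  stopifnot(inherits(genome, "diploid_genome"), pad >= 0)
  pad <- as.integer(pad)
  min_homozygous_run <- as.integer(min_homozygous_run)
  if (min_homozygous_run <= 2L * pad)
    stop("min_homozygous_run must exceed 2 x pad")
  v <- genome$variants
  LA <- nchar(genome$hap_a); LB <- nchar(genome$hap_b)
  if (!nrow(v)) {
    tab <- data.frame(id = "htg0001", class = "HOMOTIG", source = "BOTH",
                      start_a = 1L, end_a = LA, start_b = 1L, end_b = LB,
                      partner = NA_character_, stringsAsFactors = FALSE)
    contigs <- stats::setNames(genome$hap_a, "htg0001")
    return(structure(list(contigs = contigs, table = tab, pad = pad,
                          min_homozygous_run = min_homozygous_run),
                     class = "truth_contigs"))
  }
  run_before <- c(v$pos[1] - 1L,
                  v$pos[-1] - v$foot_end_a[-nrow(v)] - 1L)
  new_block <- run_before >= min_homozygous_run
  new_block[1] <- TRUE
  blk <- cumsum(new_block)
  # per-block variant index ranges
  first <- match(unique(blk), blk)
  last <- length(blk) - match(unique(blk), rev(blk)) + 1L
  off_after <- cumsum(v$len_change)
  off_before <- c(0L, off_after[-length(off_after)])
  blocks <- data.frame(
    start_a = pmax(1L, v$pos[first] - pad),
    end_a = pmin(LA, v$foot_end_a[last] + pad))
  # genome-edge runs shorter than the threshold extend the flanking block
  if (v$pos[1] - 1L < min_homozygous_run) blocks$start_a[1] <- 1L
  if (LA - v$foot_end_a[nrow(v)] < min_homozygous_run)
    blocks$end_a[nrow(blocks)] <- LA
  blocks$start_b <- blocks$start_a + off_before[first]
  blocks$end_b <- blocks$end_a + off_after[last]
  blocks$end_b <- pmin(LB, pmax(blocks$start_b, blocks$end_b))
  nb <- nrow(blocks)
  # homotigs: full homozygous runs between consecutive blocks' variants,
  # plus qualifying genome-edge runs
  ho_s <- integer(); ho_e <- integer()
  if (blocks$start_a[1] > 1L) { ho_s <- 1L; ho_e <- v$pos[first[1]] - 1L }
  if (nb > 1L) {
    ho_s <- c(ho_s, v$foot_end_a[last[-nb]] + 1L)
    ho_e <- c(ho_e, v$pos[first[-1]] - 1L)
  }
  if (blocks$end_a[nb] < LA) {
    ho_s <- c(ho_s, v$foot_end_a[last[nb]] + 1L)
    ho_e <- c(ho_e, LA)
  }
  ho_off <- vapply(ho_s, function(s)
    sum(v$len_change[v$foot_end_a < s]), integer(1))
  hid <- sprintf("htg%04d", seq_along(ho_s))
  aid <- sprintf("hetA%04d", seq_len(nb))
  bid <- sprintf("hetB%04d", seq_len(nb))
  tab <- rbind(
    data.frame(id = hid, class = "HOMOTIG", source = "BOTH",
               start_a = ho_s, end_a = ho_e,
               start_b = ho_s + ho_off, end_b = ho_e + ho_off,
               partner = NA_character_, stringsAsFactors = FALSE),
    data.frame(id = aid, class = "HETEROTIG", source = "A",
               start_a = blocks$start_a, end_a = blocks$end_a,
               start_b = NA_integer_, end_b = NA_integer_,
               partner = bid, stringsAsFactors = FALSE),
    data.frame(id = bid, class = "HETEROTIG", source = "B",
               start_a = NA_integer_, end_a = NA_integer_,
               start_b = blocks$start_b, end_b = blocks$end_b,
               partner = aid, stringsAsFactors = FALSE))
  seqs <- character(nrow(tab))
  is_b <- tab$source == "B"
  seqs[!is_b] <- substring(genome$hap_a, tab$start_a[!is_b], tab$end_a[!is_b])
  seqs[is_b] <- substring(genome$hap_b, tab$start_b[is_b], tab$end_b[is_b])
  contigs <- stats::setNames(seqs, tab$id)
  structure(list(contigs = contigs, table = tab, pad = pad,
                 min_homozygous_run = min_homozygous_run),
            class = "truth_contigs")
}

#' @export
print.truth_contigs <- function(x, ...) {
  tb <- table(x$table$class)
  cat("truth contig set:", sum(tb), "contigs (",
      tb[["HOMOTIG"]] %||% 0, "homotigs,",
      sum(x$table$class == "HETEROTIG") / 2, "heterotig pairs )\n")
  invisible(x)
}

#' Assign simulated reads to truth contigs
#'
#' Mirrors a stringent unique-placement aligner on the truth geometry: a read
#' containing a variant maps to its haplotype's heterotig; a variant-free
#' read fully inside a homozygous run maps to the homotig (placements from
#' both haplotypes collapse); a variant-free read fully inside a
#' heterozygous block matches both heterotigs and is suppressed; a read
#' spanning a contig boundary is unmapped.
#'
#' @param truth a `truth_contigs` object.
#' @param genome the generating `diploid_genome`.
#' @param reads a `sim_reads` table.
#' @return data.table with one row per read end: read_id, pair_id, mate,
#'   hap, contig (NA when unplaced), start, end (0-based half-open on the
#'   contig), strand, reason ("mapped", "ambiguous", "boundary").
#' @export
assign_reads_to_contigs <- function(truth, genome, reads) {
  m <- expand_mates(reads)
  v <- genome$variants
  tab <- truth$table
  out <- vector("list", 2L)
  for (hi in 1:2) {
    h <- c("A", "B")[hi]
    mm <- m[hap == h]
    if (h == "A") {
      fs <- v$pos; fe <- v$foot_end_a
      het <- tab[tab$class == "HETEROTIG" & tab$source == "A", ]
      hs <- het$start_a; he <- het$end_a
      hos <- tab$start_a[tab$class == "HOMOTIG"]
      hoe <- tab$end_a[tab$class == "HOMOTIG"]
    } else {
      fs <- v$pos_b; fe <- v$foot_end_b
      het <- tab[tab$class == "HETEROTIG" & tab$source == "B", ]
      hs <- het$start_b; he <- het$end_b
      hos <- tab$start_b[tab$class == "HOMOTIG"]
      hoe <- tab$end_b[tab$class == "HOMOTIG"]
    }
    homo_ids <- tab$id[tab$class == "HOMOTIG"]
    has_var <- if (length(fs)) {
      idx <- findInterval(mm$e, fs)
      idx >= 1L & fe[pmax(idx, 1L)] >= mm$s
    } else rep(FALSE, nrow(mm))
    contig <- rep(NA_character_, nrow(mm))
    cstart <- rep(NA_integer_, nrow(mm))
    reason <- rep("boundary", nrow(mm))
    # variant reads -> heterotig of this haplotype
    if (any(has_var) && nrow(het)) {
      bi <- findInterval(mm$s[has_var], hs)
      ok <- bi >= 1L & mm$e[has_var] <= he[pmax(bi, 1L)] &
        mm$s[has_var] >= hs[pmax(bi, 1L)]
      hit <- which(has_var)[ok]
      contig[hit] <- het$id[bi[ok]]
      cstart[hit] <- hs[bi[ok]]
      reason[hit] <- "mapped"
    }
    # variant-free reads -> homotig when fully contained
    novar <- which(!has_var)
    if (length(novar) && length(hos)) {
      oi <- findInterval(mm$s[novar], hos)
      ok <- oi >= 1L & mm$e[novar] <= hoe[pmax(oi, 1L)] &
        mm$s[novar] >= hos[pmax(oi, 1L)]
      hit <- novar[ok]
      contig[hit] <- homo_ids[oi[ok]]
      cstart[hit] <- hos[oi[ok]]
      reason[hit] <- "mapped"
    }
    # variant-free reads fully inside a het block: ambiguous between the
    # two homologous heterotigs -> suppressed
    left <- which(is.na(contig) & !has_var)
    if (length(left) && nrow(het)) {
      bi <- findInterval(mm$s[left], hs)
      amb <- bi >= 1L & mm$e[left] <= he[pmax(bi, 1L)] &
        mm$s[left] >= hs[pmax(bi, 1L)]
      reason[left[amb]] <- "ambiguous"
    }
    res <- mm[, .(read_id, pair_id, mate, hap, strand)]
    res[, contig := contig]
    res[, start := mm$s - cstart]          # 0-based on contig
    res[, end := mm$e - cstart + 1L]
    res[, reason := reason]
    out[[hi]] <- res
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, pair_id, mate)
  res[]
}

#' Write simulated alignments in a chosen dialect
#'
#' Lifts each placed read onto its containing contig and writes the
#' requested format; unplaced reads are emitted as unmapped records in SAM
#' (and silently absent from the hit-only Bowtie/BLAST dialects).
#'
#' @param assignments output of [assign_reads_to_contigs()].
#' @param truth the `truth_contigs` object (contig lengths for the SAM
#'   header).
#' @param path output file.
#' @param format "sam", "bowtie", or "blast".
#' @param genome optional `diploid_genome`; when supplied, SAM/Bowtie records
#'   carry real read sequences, otherwise "*" placeholders (SAM only).
#' @param reads the `sim_reads` table (required with `genome`).
#' @return the path, invisibly.
#' @export
emit_alignments <- function(assignments, truth, path,
                            format = c("sam", "bowtie", "blast"),
                            genome = NULL, reads = NULL) {
  format <- match.arg(format)
  a <- data.table::as.data.table(assignments)
  seqs <- NULL
  if (!is.null(genome)) {
    if (is.null(reads)) stop("reads table required when genome is supplied")
    sq <- sim_read_seqs(genome, reads)
    seqs <- stats::setNames(sq$seq, sq$read_id)
  }
  rl <- a$end - a$start
  if (format == "sam") {
    clen <- nchar(truth$contigs)
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(clen), clen))
    mapped <- !is.na(a$contig)
    flag <- 1L + ifelse(a$mate == 1L, 64L, 128L) +
      ifelse(a$strand == "-", 16L, 0L) + ifelse(mapped, 0L, 4L)
    seqf <- if (is.null(seqs)) "*" else seqs[a$read_id]
    lines <- paste(a$pair_id, flag,
                   ifelse(mapped, a$contig, "*"),
                   ifelse(mapped, a$start + 1L, 0L),
                   ifelse(mapped, 60L, 0L),
                   ifelse(mapped, paste0(rl, "M"), "*"),
                   "*", 0L, 0L, seqf, "*", sep = "\t")
    writeLines(c(hdr, lines), path)
  } else if (format == "bowtie") {
    b <- a[!is.na(contig)]
    sq <- if (is.null(seqs)) strrep("N", b$end - b$start) else seqs[b$read_id]
    lines <- paste(b$read_id, b$strand, b$contig, b$start, sq,
                   strrep("I", b$end - b$start), 0L, "", sep = "\t")
    writeLines(lines, path)
  } else {
    b <- a[!is.na(contig)]
    len <- b$end - b$start
    ss <- ifelse(b$strand == "+", b$start + 1L, b$end)
    se <- ifelse(b$strand == "+", b$end, b$start + 1L)
    lines <- paste(b$read_id, b$contig, "100.000", len, 0L, 0L,
                   1L, len, ss, se, "0.0", 2 * len, sep = "\t")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Generate a complete seeded truth universe
#'
#' Convenience wrapper tying the generator stages together: genome, one
#' fragment library per requested insert size, truth contigs, read-to-contig
#' assignments, and the per-contig depth table.
#'
#' @param length genome length.
#' @param het_rate,indel_fraction variant parameters
#'   (see [generate_diploid()]).
#' @param inserts list of c(mean, sd) per library, in scaffolding rank order.
#' @param coverage per-haplotype fold coverage per library.
#' @param read_len read length.
#' @param pad,min_homozygous_run truth-contig geometry
#'   (see [simulate_truth_contigs()]).
#' @param seed master RNG seed (library seeds are derived from it).
#' @return list of class `truth_universe`: genome, truth, libraries
#'   (data.frame: name, mean_insert, rank), reads (list per library),
#'   assignments (list per library), depths (named vector), provenance
#'   (named "A"/"B" per read id), membership (list contig -> read ids).
#' @export
simulate_universe <- function(length = 5e5, het_rate = 0.04,
                              indel_fraction = 0.1,
                              inserts = list(c(400, 50), c(1000, 100)),
                              coverage = 40, read_len = 75L, pad = 74L,
                              min_homozygous_run = 150L, seed = 1,
                              placement = "blocks", within_rate = 0.1,
                              run_mean = 400) {
  genome <- generate_diploid(length, het_rate, indel_fraction, seed = seed,
                             placement = placement,
                             within_rate = within_rate, run_mean = run_mean)
  truth <- simulate_truth_contigs(genome, pad, min_homozygous_run)
  libs <- data.frame(
    name = sprintf("ins%d", vapply(inserts, `[`, 0, 1L)),
    mean_insert = as.integer(vapply(inserts, `[`, 0, 1L)),
    rank = seq_along(inserts), stringsAsFactors = FALSE)
  reads <- list(); assignments <- list()
  for (i in seq_along(inserts)) {
    lib_seed <- as.integer((as.double(seed) * 1000 + i) %% 2147483647)
    reads[[libs$name[i]]] <- simulate_paired_reads(
      genome, read_len = read_len, insert_mean = inserts[[i]][1],
      insert_sd = inserts[[i]][2], coverage = coverage,
      seed = lib_seed, library = libs$name[i])
    assignments[[libs$name[i]]] <-
      assign_reads_to_contigs(truth, genome, reads[[libs$name[i]]])
  }
  asn <- data.table::rbindlist(assignments)
  placed <- asn[!is.na(contig)]
  dsum <- placed[, .(bases = sum(end - start)), by = contig]
  clen <- nchar(truth$contigs)
  depths <- stats::setNames(dsum$bases / clen[dsum$contig], dsum$contig)
  prov <- placed[, .(hap = hap[1]), by = read_id]
  provenance <- stats::setNames(prov$hap, prov$read_id)
  membership <- split(placed$read_id, placed$contig)
  structure(list(genome = genome, truth = truth, libraries = libs,
                 reads = reads, assignments = assignments, depths = depths,
                 provenance = provenance, membership = membership,
                 read_len = as.integer(read_len), coverage = coverage,
                 seed = seed),
            class = "truth_universe")
}

#' Write a truth universe to disk
#'
#' Emits the contig FASTA, per-library alignment files in the requested
#' dialect, the depth table, the library configuration, and truth tables
#' (contig truth TSV, read-provenance TSV, contig-membership TSV).
#'
#' @param universe a `truth_universe`.
#' @param dir output directory (created if needed).
#' @param format alignment dialect for the emitted files.
#' @param with_seqs carry real read sequences in the alignment files?
#' @return named list of written paths.
#' @export
write_universe <- function(universe, dir, format = "sam", with_seqs = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list()
  p$contigs <- file.path(dir, "contigs.fasta")
  write_contigs(universe$truth$contigs, p$contigs)
  p$depths <- file.path(dir, "depths.tsv")
  write_depth_table(universe$depths, p$depths)
  ext <- switch(format, sam = "sam", bowtie = "bowtie.txt", blast = "blast.tsv")
  p$alignments <- character()
  cfg <- character()
  for (i in seq_len(nrow(universe$libraries))) {
    nm <- universe$libraries$name[i]
    f <- file.path(dir, paste0(nm, ".", ext))
    emit_alignments(universe$assignments[[nm]], universe$truth, f, format,
                    genome = if (with_seqs) universe$genome else NULL,
                    reads = if (with_seqs) universe$reads[[nm]] else NULL)
    p$alignments <- c(p$alignments, f)
    cfg <- c(cfg, "[LIB]",
             paste0("name=", nm),
             paste0("avg_ins=", universe$libraries$mean_insert[i]),
             paste0("rank=", universe$libraries$rank[i]),
             paste0("format=", format),
             paste0("map=", f))
  }
  p$config <- file.path(dir, "libraries.cfg")
  writeLines(cfg, p$config)
  p$truth_contigs <- file.path(dir, "truth_contigs.tsv")
  utils::write.table(universe$truth$table, p$truth_contigs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p$provenance <- file.path(dir, "read_provenance.tsv")
  utils::write.table(
    data.frame(read_id = names(universe$provenance),
               haplotype = unname(universe$provenance)),
    p$provenance, sep = "\t", quote = FALSE, row.names = FALSE)
  p$membership <- file.path(dir, "contig_membership.tsv")
  mem <- data.frame(
    contig = rep(names(universe$membership),
                 lengths(universe$membership)),
    read_id = unlist(universe$membership, use.names = FALSE))
  utils::write.table(mem, p$membership, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p
}
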