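# The end-to-end diploid scaffolding driver: graph construction per library
# rank, bubble detection and homolog classification at rank 1, greedy chain
# linking at every rank, chain phasing, and haploid scaffold emission.

# merge per-library scaffold graphs of one rank: weights add, gap estimates
# combine as support-weighted means
merge_graphs <- function(graphs) {
  if (length(graphs) == 1L) return(graphs[[1]])
  ed <- data.table::rbindlist(lapply(graphs, function(g) g$edges))
  merged <- ed[, .(weight = sum(weight),
                   gap = sum(gap * weight) / sum(weight)),
               by = .(c_a, e_a, c_b, e_b)]
  merged[, excluded := FALSE]
  data.table::setorder(merged, c_a, e_a, c_b, e_b)
  g <- graphs[[1]]
  g$edges <- merged
  g
}

#' Scaffold a diploid contig set into two phased haploid scaffold sets
#'
#' Runs the full pipeline: per-rank scaffold graph construction from paired
#' alignments, minimum-support filtering, repeat flagging, perfect-bubble
#' detection, classifier training on perfect bubbles, classification of
#' imperfect bubbles, conflict-checked bubble acceptance, greedy chain
#' linking (ranks beyond the first only link and phase), chain phasing by
#' cross-bubble read-pair votes, and emission of two haploid sequences per
#' chain.
#'
#' @param contigs contig set (named character vector, or FASTA path).
#' @param libraries library table ([read_library_config()] output or a path
#'   to a config file): name, mean_insert, rank, format, files.
#' @param depths optional named per-contig depth vector or TSV path; absent
#'   depths put the classifier in reduced-feature mode.
#' @param alignments optional named list (library name -> pre-parsed
#'   alignment table) bypassing file reading.
#' @param min_support minimum edge support (default 2).
#' @param allow_multimapped allow multiply-mapped read ends (default FALSE).
#' @param degree_factor,depth_factor repeat-flagging multipliers.
#' @param learner,negative_ratio,threshold,min_training classifier options
#'   (see [train_classifier()] and [build_training_set()]).
#' @param min_edges minimum present edges for imperfect candidates.
#' @param gap_floor minimum emitted N-run length.
#' @param identity_method [pairwise_identity()] engine selection.
#' @param seed RNG seed (negative sampling; learner initialisation).
#' @param verbose print progress messages.
#' @return an object of class `dipscaffold_result`.
#' @export
scaffold_diploid <- function(contigs, libraries, depths = NULL,
                             alignments = NULL, min_support = 2L,
                             allow_multimapped = FALSE, degree_factor = 5,
                             depth_factor = 3, learner = "logistic",
                             negative_ratio = 1, threshold = 0.5,
                             min_training = 10L, min_edges = 2L,
                             gap_floor = 10L, identity_method = "auto",
                             seed = 1L, verbose = FALSE) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- read_contigs(contigs)
  if (is.character(libraries)) libraries <- read_library_config(libraries)
  if (is.character(depths) && length(depths) == 1L)
    depths <- read_depth_table(depths, contigs)
  say <- function(...) if (verbose) message(...)

  libraries <- libraries[order(libraries$rank), , drop = FALSE]
  aln <- list()
  for (i in seq_len(nrow(libraries))) {
    nm <- libraries$name[i]
    if (!is.null(alignments) && nm %in% names(alignments)) {
      aln[[nm]] <- data.table::as.data.table(alignments[[nm]])
    } else {
      files <- libraries$files[[i]]
      parts <- lapply(files, read_alignments,
                      format = libraries$format[i], contigs = contigs)
      aln[[nm]] <- data.table::rbindlist(parts)
      aln[[nm]][, mult := .N, by = read_id]
    }
    say("library ", nm, ": ", nrow(aln[[nm]]), " alignment records")
  }

  ranks <- sort(unique(libraries$rank))
  graphs <- list()
  pair_status <- list()
  build_rank <- function(r) {
    libs <- which(libraries$rank == r)
    gs <- lapply(libs, function(i) {
      b <- build_scaffold_graph(aln[[libraries$name[i]]], contigs,
                                libraries$mean_insert[i],
                                allow_multimapped = allow_multimapped)
      ps <- b$pair_status
      ps[, library := libraries$name[i]]
      pair_status[[libraries$name[i]]] <<- ps
      b$graph
    })
    merge_graphs(gs)
  }

  g1 <- build_rank(ranks[1])
  g1 <- apply_min_support(g1, min_support)
  g1 <- flag_repeats(g1, depths, degree_factor, depth_factor)
  graphs[[as.character(ranks[1])]] <- g1
  say("rank ", ranks[1], " graph: ", nrow(g1$edges), " edges, ",
      length(g1$repeats), " repeat-flagged contigs")

  perfect <- find_perfect_bubbles(g1)
  imperfect <- enumerate_imperfect_bubbles(g1, perfect, min_edges = min_edges)
  say(nrow(perfect), " perfect bubbles, ", nrow(imperfect),
      " imperfect candidates")

  classifier <- NULL
  training_set <- NULL
  classified <- cbind(empty_imperfect_table(),
                      probability = numeric(), is_homolog = logical())
  if (nrow(perfect) >= min_training) {
    training_set <- build_training_set(
      perfect, g1, contigs, depths = depths,
      negative_ratio = negative_ratio, seed = seed,
      min_training = min_training, method = identity_method)
    classifier <- train_classifier(training_set, learner = learner,
                                   seed = seed, threshold = threshold)
    say("classifier trained: accuracy ",
        sprintf("%.3f", classifier$train_accuracy))
    if (nrow(imperfect)) {
      modal <- training_set$modal_depth
      # classify each candidate heterotig pair once; a pair may appear in
      # several alternative bubble constructions
      pk <- paste(imperfect$a, imperfect$b, sep = "|")
      first <- which(!duplicated(pk))
      uprob <- vapply(first, function(i) {
        fv <- compute_feature_vector(
          contigs[[imperfect$a[i]]], contigs[[imperfect$b[i]]],
          depth_a = if (!is.null(depths)) depths[imperfect$a[i]][[1]] else NULL,
          depth_b = if (!is.null(depths)) depths[imperfect$b[i]][[1]] else NULL,
          modal_depth = modal, method = identity_method)
        classify_pair(classifier, fv)$probability
      }, numeric(1))
      prob <- uprob[match(pk, pk[first])]
      classified <- cbind(imperfect, probability = prob,
                          is_homolog = prob >= threshold)
    }
  } else if (nrow(perfect) > 0L || nrow(imperfect) > 0L) {
    warning("only ", nrow(perfect), " perfect bubbles (< ", min_training,
            "): skipping classification, emitting bubble-only scaffolds")
  }

  accepted_imp <- classified[classified$is_homolog, , drop = FALSE]
  acc <- accept_bubbles(perfect, accepted_imp)
  included <- acc$included
  say(nrow(acc$accepted), " bubbles accepted (",
      sum(acc$accepted$origin == "perfect"), " perfect)")

  blocked <- heterotig_end_keys(acc$accepted)
  included <- greedy_link(g1, included, blocked)
  for (r in ranks[-1]) {
    gr <- build_rank(r)
    gr <- apply_min_support(gr, min_support)
    gr$repeats <- g1$repeats
    graphs[[as.character(r)]] <- gr
    included <- greedy_link(gr, included, blocked)
  }

  chains <- build_chains(included, contigs, g1$repeats)
  het_links <- tabulate_het_links(aln, acc$accepted)
  phasing <- phase_chains(chains, het_links)
  scaffolds <- emit_haplotypes(chains, phasing, contigs, gap_floor)
  say(length(chains), " chains; ", nrow(phasing$groups), " phase groups")

  res <- structure(list(
    contigs = contigs,
    libraries = libraries[, c("name", "mean_insert", "rank", "format")],
    depths = depths,
    graphs = graphs,
    pair_status = data.table::rbindlist(pair_status),
    bubbles = list(perfect = perfect, imperfect = imperfect,
                   classified = classified, accepted = acc$accepted),
    classifier = classifier,
    training_set = training_set,
    included = included,
    chains = chains,
    het_links = het_links,
    phasing = phasing,
    scaffolds = scaffolds,
    params = list(min_support = min_support, learner = learner,
                  negative_ratio = negative_ratio, threshold = threshold,
                  min_training = min_training, gap_floor = gap_floor,
                  degree_factor = degree_factor, depth_factor = depth_factor,
                  allow_multimapped = allow_multimapped, seed = seed)),
    class = "dipscaffold_result")
  check_invariants(res)
  res
}

# cross-bubble heterotig link counts from all libraries' alignments
tabulate_het_links <- function(aln, accepted) {
  if (is.null(accepted) || !nrow(accepted)) {
    return(data.frame(contig_a = character(), contig_b = character(),
                      n_links = integer()))
  }
  hets <- unique(c(accepted$a, accepted$b))
  bub_of <- stats::setNames(rep(seq_len(nrow(accepted)), 2L),
                            c(accepted$a, accepted$b))
  out <- list()
  for (tab in aln) {
    t1 <- tab[mate == 1L & mult == 1L & contig %in% hets,
              .(pair_id, contig)]
    t2 <- tab[mate == 2L & mult == 1L & contig %in% hets,
              .(pair_id, contig)]
    j <- merge(t1, t2, by = "pair_id", suffixes = c("_x", "_y"))
    j <- j[contig_x != contig_y]
    if (!nrow(j)) next
    j <- j[bub_of[contig_x] != bub_of[contig_y]]
    if (!nrow(j)) next
    j[, `:=`(contig_a = pmin(contig_x, contig_y),
             contig_b = pmax(contig_x, contig_y))]
    out[[length(out) + 1L]] <- j[, .(n = .N), by = .(contig_a, contig_b)]
  }
  if (!length(out)) {
    return(data.frame(contig_a = character(), contig_b = character(),
                      n_links = integer()))
  }
  all <- data.table::rbindlist(out)[, .(n_links = sum(n)),
                                    by = .(contig_a, contig_b)]
  data.table::setorder(all, contig_a, contig_b)
  as.data.frame(all)
}

#' Check the structural invariants of a pipeline result
#'
#' Asserts the occupancy rule (each contig end used by at most one included
#' item), subgraph purity (every included edge belongs to an accepted bubble
#' or is a greedy link between unoccupied ends), phase-group complementarity
#' (every bubble's heterotigs in complementary groups), and output
#' conservation (every non-repeat contig appears exactly once across the
#' emitted scaffolds).
#'
#' @param result a `dipscaffold_result`.
#' @return TRUE invisibly; stops with a message otherwise.
#' @export
check_invariants <- function(result) {
  inc <- result$included
  keys <- names(inc$occ)
  if (anyDuplicated(keys))
    stop("occupancy violation: contig end used twice: ",
         keys[duplicated(keys)][1])
  for (it in inc$items) {
    if (it$type == "edge") {
      k <- c(end_key(it$c_a, it$e_a), end_key(it$c_b, it$e_b))
      if (!all(k %in% keys)) stop("included edge with unregistered end")
    }
  }
  acc <- result$bubbles$accepted
  ph <- result$phasing
  if (nrow(acc) && nrow(ph$groups)) {
    asg <- ph$assignment
    comp <- stats::setNames(ph$groups$complement, ph$groups$group)
    for (i in seq_len(nrow(acc))) {
      ga <- asg[acc$a[i]]; gb <- asg[acc$b[i]]
      if (is.na(ga) || is.na(gb) || comp[ga] != gb)
        stop("bubble heterotigs ", acc$a[i], "/", acc$b[i],
             " not in complementary phase groups")
    }
  }
  lay <- result$scaffolds$layout
  emitted <- lay$contig
  if (anyDuplicated(emitted))
    stop("contig emitted more than once: ", emitted[duplicated(emitted)][1])
  expect <- setdiff(names(result$contigs), result$graphs[[1]]$repeats)
  missing <- setdiff(expect, emitted)
  if (length(missing))
    stop("contig(s) missing from output: ",
         paste(utils::head(missing, 5), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.dipscaffold_result <- function(x, ...) {
  cat("diploid scaffolding result\n")
  cat("  contigs:", length(x$contigs), " libraries:",
      nrow(x$libraries), "\n")
  cat("  bubbles:", nrow(x$bubbles$perfect), "perfect,",
      nrow(x$bubbles$accepted), "accepted total\n")
  cat("  chains:", length(x$chains), " phase groups:",
      nrow(x$phasing$groups), "\n")
  cat("  scaffolds:", length(x$scaffolds$hap1), "per haplotype\n")
  invisible(x)
}

#' @export
summary.dipscaffold_result <- function(object, ...) {
  x <- object
  acc <- x$bubbles$accepted
  hets <- unique(c(acc$a, acc$b))
  het_bases <- sum(nchar(x$contigs[hets]))
  phased <- x$phasing$members$contig
  phased_bases <- sum(nchar(x$contigs[phased]))
  s <- list(
    n_contigs = length(x$contigs),
    n_scaffolds = length(x$scaffolds$hap1),
    n_perfect_bubbles = nrow(x$bubbles$perfect),
    n_classified_pairs = sum(acc$origin == "imperfect"),
    n_accepted_pairs = nrow(acc),
    n_phase_groups = nrow(x$phasing$groups),
    pct_pairs_phased = if (nrow(acc))
      100 * length(intersect(hets, phased)) / length(hets) else NA_real_,
    het_bases = het_bases,
    phased_bases = phased_bases,
    pct_het_bases_phased = if (het_bases > 0)
      100 * phased_bases / het_bases else NA_real_,
    phasing_conflicts = x$phasing$conflicts)
  class(s) <- "summary.dipscaffold_result"
  s
}

#' @export
print.summary.dipscaffold_result <- function(x, ...) {
  cat("diploid scaffolding summary\n")
  cat(sprintf("  %d contigs combined into %d scaffolds\n",
              x$n_contigs, x$n_scaffolds))
  cat(sprintf("  %d perfect bubbles for training; %d further pairs classified\n",
              x$n_perfect_bubbles, x$n_classified_pairs))
  cat(sprintf("  %d homolog pairs phased into %d phase groups (%.1f%% of pairs)\n",
              x$n_accepted_pairs, x$n_phase_groups, x$pct_pairs_phased))
  cat(sprintf("  %d heterotig bases, %.1f%% phased\n",
              x$het_bases, x$pct_het_bases_phased))
  invisible(x)
}

#' Plot depth densities by contig class
#'
#' Histogram of per-contig sequencing depth for trained heterotigs,
#' classified heterotigs, and remaining (homotig-like) contigs; requires a
#' depth table.
#'
#' @param x a `dipscaffold_result`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.dipscaffold_result <- function(x, ...) {
  if (is.null(x$depths)) stop("no depth table in this result")
  acc <- x$bubbles$accepted
  trained <- unique(c(x$bubbles$perfect$a, x$bubbles$perfect$b))
  cls <- setdiff(unique(c(acc$a, acc$b)), trained)
  grp <- ifelse(names(x$depths) %in% trained, "trained",
                ifelse(names(x$depths) %in% cls, "classified", "other"))
  cols <- c(trained = "#d95f02", classified = "#7570b3", other = "#1b9e77")
  br <- pretty(x$depths, 40)
  h0 <- graphics::hist(x$depths, breaks = br, plot = FALSE)
  graphics::plot(h0, col = "grey90", border = NA,
                 main = "contig sequencing depth by class",
                 xlab = "fold coverage", ...)
  for (g in unique(grp)) {
    hg <- graphics::hist(x$depths[grp == g], breaks = br, plot = FALSE)
    graphics::lines(hg$mids, hg$counts, col = cols[[g]], lwd = 2)
  }
  graphics::legend("topright", legend = names(cols), col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Emits hap1.fasta / hap2.fasta, the scaffold layout TSV, phase-group TSV,
#' PairStatus TSV, bubble report TSV, and the rank-1 scaffold graph in DOT
#' format with excluded edges dashed.
#'
#' @param result a `dipscaffold_result`.
#' @param dir output directory.
#' @return named list of written paths.
#' @export
write_scaffold_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list()
  p$hap1 <- file.path(dir, "hap1.fasta")
  p$hap2 <- file.path(dir, "hap2.fasta")
  write_contigs(result$scaffolds$hap1, p$hap1)
  write_contigs(result$scaffolds$hap2, p$hap2)
  p$layout <- file.path(dir, "scaffold_layout.tsv")
  lay <- result$scaffolds$layout
  lay$gap_after[is.na(lay$gap_after)] <- ""
  utils::write.table(lay, p$layout, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p$phase_groups <- file.path(dir, "phase_groups.tsv")
  pg <- merge(result$phasing$members, result$phasing$groups, by = "group")
  pg <- pg[order(pg$group, pg$contig),
           c("group", "complement", "chain", "contig")]
  utils::write.table(pg, p$phase_groups, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p$pair_status <- file.path(dir, "pair_status.tsv")
  write_pair_status(result$pair_status, p$pair_status)
  p$bubbles <- file.path(dir, "bubbles.tsv")
  bt <- result$bubbles$accepted
  utils::write.table(bt, p$bubbles, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p$dot <- file.path(dir, "scaffold_graph.dot")
  write_dot(result$graphs[[1]], p$dot, show_excluded = TRUE,
            highlight = unique(c(bt$a, bt$b)))
  p
}
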