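# Diploid scaffolding quality metrics computed against truth labels: contig
# sequencing depth, contig homogeneity (fraction of haplotype-A reads),
# phase-group homogeneity, and heterogeneity between complementary phase
# groups. All per-contig analyses are restricted to contigs longer than
# 100 bases.

#' Contig sequencing depth
#'
#' Average number of reads contributing to each contig position: the summed
#' aligned length of the member reads divided by the contig length.
#'
#' @param contig_length contig length (bp, > 0).
#' @param read_lengths aligned lengths of the member reads (bp).
#' @return fold coverage (0 when no members).
#' @export
contig_depth <- function(contig_length, read_lengths) {
  stopifnot(contig_length > 0)
  if (!length(read_lengths)) return(0)
  sum(read_lengths) / contig_length
}

#' Contig homogeneity
#'
#' Fraction of a contig's member reads that derive from haplotype A.
#' Heterotigs should approach 0 or 1, homotigs 0.5.
#'
#' @param members member read ids.
#' @param provenance named vector mapping read id to "A" or "B".
#' @return value in \[0, 1\].
#' @export
contig_homogeneity <- function(members, provenance) {
  if (!length(members)) stop("contig has no member reads")
  h <- provenance[members]
  if (anyNA(h)) stop("provenance missing for some member reads")
  mean(h == "A")
}

#' Phase-group homogeneity
#'
#' Read-weighted fraction of haplotype-A reads across a group's member
#' contigs: total A reads in the group divided by total reads in the group.
#'
#' @param group member contig ids.
#' @param memberships list mapping contig id to member read ids.
#' @param provenance named read-id to haplotype vector.
#' @return value in \[0, 1\].
#' @export
phase_group_homogeneity <- function(group, memberships, provenance) {
  if (!length(group)) stop("empty phase group")
  reads <- unlist(memberships[group], use.names = FALSE)
  if (!length(reads)) stop("phase group has no member reads")
  contig_homogeneity(reads, provenance)
}

#' Heterogeneity between complementary phase groups
#'
#' Absolute difference in the haplotype-A read fraction between two
#' complementary phase groups. Accurate phasing drives this toward 1.
#'
#' @param group_m,group_n member contig ids of the two groups.
#' @param memberships list mapping contig id to member read ids.
#' @param provenance named read-id to haplotype vector.
#' @param phase_groups optional phasing result ([phase_chains()]); when
#'   given together with `ids`, complementarity is verified.
#' @param ids optional c(group_m_id, group_n_id) used with `phase_groups`.
#' @return value in \[0, 1\].
#' @export
phase_pair_heterogeneity <- function(group_m, group_n, memberships,
                                     provenance, phase_groups = NULL,
                                     ids = NULL) {
  if (!length(group_m) || !length(group_n)) stop("empty phase group")
  if (!is.null(phase_groups) && !is.null(ids)) {
    comp <- phase_groups$groups$complement[
      match(ids[1], phase_groups$groups$group)]
    if (is.na(comp) || comp != ids[2])
      stop("groups ", ids[1], " and ", ids[2], " are not complementary")
  }
  abs(phase_group_homogeneity(group_m, memberships, provenance) -
        phase_group_homogeneity(group_n, memberships, provenance))
}

#' Depth-based precision/recall summary of heterotig classification
#'
#' Over contigs longer than 100 bases: the fraction of heterotig-classified
#' contigs whose sequencing depth lies below the threshold (precision-like),
#' and the fraction of below-threshold contigs that were classified as
#' heterotigs (recall-like). The default threshold is 1.5 x the modal depth,
#' the generalisation of a hard cutoff at 1.5 x the haploid mode.
#'
#' @param depths named per-contig depth vector.
#' @param lengths named per-contig length vector.
#' @param classified_het ids of contigs called heterotigs (trained or
#'   classified).
#' @param depth_threshold cutoff (default 1.5 x modal depth).
#' @return list: precision, recall (NA when denominators are empty), counts
#'   (n_classified, n_classified_below, n_below, threshold).
#' @export
classification_summary <- function(depths, lengths, classified_het,
                                   depth_threshold = NULL) {
  keep <- names(depths)[lengths[names(depths)] > 100L]
  depths <- depths[keep]
  if (is.null(depth_threshold))
    depth_threshold <- 1.5 * depth_mode(depths)
  cls <- intersect(classified_het, names(depths))
  below <- names(depths)[depths < depth_threshold]
  n_cls <- length(cls)
  n_cls_below <- length(intersect(cls, below))
  n_below <- length(below)
  list(precision = if (n_cls) n_cls_below / n_cls else NA_real_,
       recall = if (n_below) n_cls_below / n_below else NA_real_,
       counts = list(n_classified = n_cls, n_classified_below = n_cls_below,
                     n_below = n_below, threshold = depth_threshold))
}

#' Histogram export of a metric's density
#'
#' Headless-friendly density export: bin counts as a two-column data.frame
#' (bin center, count).
#'
#' @param values numeric vector.
#' @param bin_width bin width.
#' @return data.frame(value, count).
#' @export
metric_histogram <- function(values, bin_width = 0.02) {
  if (!length(values)) return(data.frame(value = numeric(), count = integer()))
  idx <- floor(values / bin_width + 0.5)
  tab <- table(idx)
  data.frame(value = as.numeric(names(tab)) * bin_width,
             count = as.integer(tab))
}

#' Full truth-based evaluation of a scaffolding run
#'
#' Computes the four quality metrics for a pipeline result against its
#' generating truth universe: per-contig depth and homogeneity (with
#' trained / classified / homotig class labels), per-group and per-pair
#' phasing metrics, and the depth-threshold classification summary.
#'
#' @param result a `dipscaffold_result` from [scaffold_diploid()].
#' @param universe the `truth_universe` the inputs came from.
#' @param depth_threshold see [classification_summary()].
#' @return list of class `dipscaffold_eval`: contig_metrics (data.frame),
#'   group_homogeneity (data.frame), pair_heterogeneity (data.frame),
#'   classification (list), recovery (list: true pairs, recovered pairs,
#'   fraction).
#' @export
evaluate_scaffolding <- function(result, universe, depth_threshold = NULL) {
  mem <- universe$membership
  prov <- universe$provenance
  lens <- nchar(universe$truth$contigs)
  rl <- universe$read_len
  acc <- result$bubbles$accepted
  trained <- unique(c(result$bubbles$perfect$a, result$bubbles$perfect$b))
  classified <- setdiff(unique(c(acc$a, acc$b)), trained)
  ids <- names(mem)
  cm <- data.frame(
    contig = ids,
    length = unname(lens[ids]),
    depth = vapply(ids, function(i)
      contig_depth(lens[[i]], rep(rl, length(mem[[i]]))), numeric(1)),
    homogeneity = vapply(ids, function(i)
      contig_homogeneity(mem[[i]], prov), numeric(1)),
    class = ifelse(ids %in% trained, "trained",
                   ifelse(ids %in% classified, "classified", "homotig")),
    stringsAsFactors = FALSE)
  cm <- cm[cm$length > 100L, , drop = FALSE]
  ph <- result$phasing
  gh <- data.frame(group = character(), homogeneity = numeric())
  het <- data.frame(group_m = character(), group_n = character(),
                    heterogeneity = numeric())
  if (!is.null(ph) && nrow(ph$groups)) {
    gmembers <- split(ph$members$contig, ph$members$group)
    gh <- data.frame(
      group = names(gmembers),
      homogeneity = vapply(gmembers, function(g)
        phase_group_homogeneity(g, mem, prov), numeric(1)),
      stringsAsFactors = FALSE)
    seen <- character()
    rows <- list()
    for (i in seq_len(nrow(ph$groups))) {
      g <- ph$groups$group[i]; cgrp <- ph$groups$complement[i]
      if (g %in% seen) next
      seen <- c(seen, g, cgrp)
      rows[[length(rows) + 1L]] <- data.frame(
        group_m = g, group_n = cgrp,
        heterogeneity = phase_pair_heterogeneity(
          gmembers[[g]], gmembers[[cgrp]], mem, prov),
        stringsAsFactors = FALSE)
    }
    if (length(rows)) het <- do.call(rbind, rows)
  }
  cls <- classification_summary(
    stats::setNames(cm$depth, cm$contig),
    stats::setNames(cm$length, cm$contig),
    c(trained, classified), depth_threshold)
  tt <- universe$truth$table
  true_pairs <- tt[tt$class == "HETEROTIG" & tt$source == "A",
                   c("id", "partner")]
  found <- paste(pmin(acc$a, acc$b), pmax(acc$a, acc$b))
  truthkey <- paste(pmin(true_pairs$id, true_pairs$partner),
                    pmax(true_pairs$id, true_pairs$partner))
  recovery <- list(
    n_true = length(truthkey),
    n_recovered = sum(truthkey %in% found),
    n_called = length(found),
    n_false = sum(!found %in% truthkey),
    fraction = if (length(truthkey)) mean(truthkey %in% found) else NA_real_)
  structure(list(contig_metrics = cm, group_homogeneity = gh,
                 pair_heterogeneity = het, classification = cls,
                 recovery = recovery),
            class = "dipscaffold_eval")
}

#' @export
print.dipscaffold_eval <- function(x, ...) {
  cat("diploid scaffolding evaluation\n")
  cat(sprintf("  true homolog pairs recovered: %d / %d (%.1f%%)\n",
              x$recovery$n_recovered, x$recovery$n_true,
              100 * x$recovery$fraction))
  cat(sprintf("  classification: precision %.3f, recall %.3f (depth < %.1f)\n",
              x$classification$precision, x$classification$recall,
              x$classification$counts$threshold))
  if (nrow(x$group_homogeneity)) {
    pure <- mean(x$group_homogeneity$homogeneity <= 0.05 |
                   x$group_homogeneity$homogeneity >= 0.95)
    cat(sprintf("  phase groups: %d, %.1f%% pure (hom <= 0.05 or >= 0.95)\n",
                nrow(x$group_homogeneity), 100 * pure))
  }
  if (nrow(x$pair_heterogeneity))
    cat(sprintf("  complementary pairs with heterogeneity >= 0.9: %.1f%%\n",
                100 * mean(x$pair_heterogeneity$heterogeneity >= 0.9)))
  invisible(x)
}
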