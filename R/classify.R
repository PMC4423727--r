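# Binary classification of candidate homologous contig pairs. Training
# examples come from perfect bubbles (assumed true homolog pairs); negatives
# are seeded random non-adjacent contig pairs. The learner is pluggable:
# logistic regression (default), a single-hidden-layer perceptron, or a
# linear SVM.

FEATURES_FULL <- c("length_ratio", "depth_ratio", "pct_identical",
                   "pct_length_alignment", "depth_prop_a", "depth_prop_b")
FEATURES_REDUCED <- c("length_ratio", "pct_identical", "pct_length_alignment")

#' Modal sequencing depth
#'
#' Center of the most populated histogram bin (bins centered on multiples of
#' `bin_width`); ties break toward the lower bin. When contig lengths are
#' supplied, only contigs of length >= 100 bases contribute.
#'
#' @param depths named numeric depth vector.
#' @param bin_width histogram bin width in fold-coverage units (default 1).
#' @param lengths optional named contig lengths for the 100-bp filter.
#' @return modal depth (numeric scalar).
#' @export
depth_mode <- function(depths, bin_width = 1, lengths = NULL) {
  if (!length(depths)) stop("empty depth table")
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (!is.null(lengths)) {
    keep <- names(depths)[lengths[names(depths)] >= 100L]
    if (length(keep)) depths <- depths[keep]
  }
  idx <- floor(depths / bin_width + 0.5)
  tab <- table(idx)
  centers <- as.numeric(names(tab)) * bin_width
  ord <- order(-as.integer(tab), centers)
  centers[ord][1]
}

#' Compute the classification feature vector for a contig pair
#'
#' Six features: length ratio min/max, depth ratio min/max, percent identical
#' matches of the best local alignment, alignment length as a percentage of
#' the shorter contig (capped at 100), and each contig's depth as a
#' proportion of the modal depth of all contigs. Without depth information
#' the three depth features are dropped (reduced-feature mode).
#'
#' @param seq_a,seq_b contig sequences.
#' @param depth_a,depth_b optional per-contig depths.
#' @param modal_depth modal depth of all contigs (required with depths).
#' @param identity optional precomputed [pairwise_identity()] result.
#' @param ... passed to [pairwise_identity()].
#' @return named numeric vector (6 features, or 3 in reduced mode).
#' @export
compute_feature_vector <- function(seq_a, seq_b, depth_a = NULL,
                                   depth_b = NULL, modal_depth = NULL,
                                   identity = NULL, ...) {
  la <- nchar(seq_a); lb <- nchar(seq_b)
  if (la == 0L || lb == 0L) stop("zero-length contig")
  if (is.null(identity)) identity <- pairwise_identity(seq_a, seq_b, ...)
  fv <- c(length_ratio = min(la, lb) / max(la, lb),
          pct_identical = identity$pct_identical,
          pct_length_alignment =
            min(100, 100 * identity$alignment_length / min(la, lb)))
  have_depth <- !is.null(depth_a) && !is.null(depth_b) &&
    !is.na(depth_a) && !is.na(depth_b)
  if (have_depth) {
    if (is.null(modal_depth)) stop("modal_depth required when depths given")
    fv <- c(fv,
            depth_ratio = min(depth_a, depth_b) / max(depth_a, depth_b),
            depth_prop_a = depth_a / modal_depth,
            depth_prop_b = depth_b / modal_depth)
    fv <- fv[FEATURES_FULL]
  } else {
    fv <- fv[FEATURES_REDUCED]
  }
  stopifnot(fv[["length_ratio"]] > 0, fv[["length_ratio"]] <= 1,
            fv[["pct_identical"]] >= 0, fv[["pct_identical"]] <= 100,
            fv[["pct_length_alignment"]] >= 0,
            fv[["pct_length_alignment"]] <= 100)
  fv
}

#' Assemble a training set from perfect bubbles
#'
#' One positive (HOMOLOG) example per perfect bubble's heterotig pair;
#' negatives are seeded random contig pairs that share no scaffold-graph edge
#' and are not perfect-bubble partners.
#'
#' @param perfect perfect-bubble table ([find_perfect_bubbles()]).
#' @param graph the `scaffold_graph` (adjacency exclusion for negatives).
#' @param contigs contig set.
#' @param depths optional named depth vector (NULL = reduced-feature mode).
#' @param negative_ratio negatives per positive (default 1).
#' @param seed RNG seed for negative sampling.
#' @param min_training minimum number of positives required (default 10).
#' @param ... passed to [pairwise_identity()].
#' @return list of class `homolog_training_set`: features (matrix), labels
#'   (factor HOMOLOG/NON_HOMOLOG), provenance (data.frame pair ids + source),
#'   modal_depth.
#' @export
build_training_set <- function(perfect, graph, contigs, depths = NULL,
                               negative_ratio = 1, seed = 1,
                               min_training = 10L, ...) {
  npos <- nrow(perfect)
  if (npos < min_training)
    stop("only ", npos, " perfect bubbles; at least ", min_training,
         " are required to train. Fall back to emitting bubble-only ",
         "scaffolds without classification.")
  lens <- nchar(contigs)
  modal <- if (!is.null(depths)) depth_mode(depths, lengths = lens) else NULL
  fv_pair <- function(x, y) {
    compute_feature_vector(contigs[[x]], contigs[[y]],
                           depth_a = if (!is.null(depths)) depths[x][[1]] else NULL,
                           depth_b = if (!is.null(depths)) depths[y][[1]] else NULL,
                           modal_depth = modal, ...)
  }
  pos <- lapply(seq_len(npos), function(i) fv_pair(perfect$a[i], perfect$b[i]))
  # adjacency lookup over all edges (even excluded ones) for the negative null
  ed <- graph$edges
  edge_keys <- if (nrow(ed)) paste(pmin(ed$c_a, ed$c_b), pmax(ed$c_a, ed$c_b))
               else character()
  pos_keys <- paste(pmin(perfect$a, perfect$b), pmax(perfect$a, perfect$b))
  pool <- setdiff(names(contigs), graph$repeats)
  n_neg <- as.integer(round(negative_ratio * npos))
  neg_pairs <- with_seed(seed, {
    chosen <- character(0); out <- list()
    guard <- 0L
    while (length(out) < n_neg && guard < 50L * n_neg + 100L) {
      guard <- guard + 1L
      p <- sample(pool, 2L)
      key <- paste(min(p), max(p))
      if (key %in% chosen || key %in% edge_keys || key %in% pos_keys) next
      chosen <- c(chosen, key)
      out[[length(out) + 1L]] <- sort(p)
    }
    out
  })
  neg <- lapply(neg_pairs, function(p) fv_pair(p[1], p[2]))
  feats <- do.call(rbind, c(pos, neg))
  labels <- factor(rep(c("HOMOLOG", "NON_HOMOLOG"),
                       c(length(pos), length(neg))),
                   levels = c("NON_HOMOLOG", "HOMOLOG"))
  prov <- data.frame(
    a = c(perfect$a, vapply(neg_pairs, `[`, "", 1L)),
    b = c(perfect$b, vapply(neg_pairs, `[`, "", 2L)),
    source = rep(c("perfect_bubble", "sampled_negative"),
                 c(length(pos), length(neg))),
    stringsAsFactors = FALSE)
  structure(list(features = feats, labels = labels, provenance = prov,
                 modal_depth = modal, seed = seed),
            class = "homolog_training_set")
}

#' Train the homolog classifier
#'
#' @param training_set a `homolog_training_set`.
#' @param learner "logistic" (stats::glm, default), "mlp"
#'   (nnet single-hidden-layer perceptron), or "svm" (e1071 linear SVM).
#' @param seed RNG seed (relevant for mlp weight init and svm probability
#'   calibration).
#' @param threshold decision threshold on P(homolog) (default 0.5; a pair is
#'   called homologous when probability >= threshold).
#' @return a `homolog_classifier` object.
#' @export
train_classifier <- function(training_set,
                             learner = c("logistic", "mlp", "svm"),
                             seed = 1, threshold = 0.5) {
  learner <- match.arg(learner)
  x <- training_set$features
  y <- training_set$labels
  if (length(unique(y)) < 2L)
    stop("training set has a single class; cannot train")
  df <- data.frame(x)
  df$.label <- y
  fit <- switch(learner,
    logistic = suppressWarnings(
      stats::glm(.label ~ ., data = df, family = stats::binomial())),
    mlp = {
      if (!requireNamespace("nnet", quietly = TRUE))
        stop("learner 'mlp' needs the nnet package")
      with_seed(seed, nnet::nnet(.label ~ ., data = df, size = 4,
                                 decay = 1e-3, maxit = 500, trace = FALSE))
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("learner 'svm' needs the e1071 package")
      with_seed(seed, e1071::svm(.label ~ ., data = df, kernel = "linear",
                                 probability = TRUE))
    })
  model <- structure(list(fit = fit, learner = learner,
                          features = colnames(x), threshold = threshold,
                          n_train = nrow(x), seed = seed),
                     class = "homolog_classifier")
  p <- predict_homolog_prob(model, x)
  model$train_accuracy <- mean((p >= threshold) == (y == "HOMOLOG"))
  model
}

predict_homolog_prob <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  df <- data.frame(x[, model$features, drop = FALSE])
  switch(model$learner,
    logistic = as.numeric(stats::predict(model$fit, df, type = "response")),
    mlp = as.numeric(stats::predict(model$fit, df, type = "raw")),
    svm = {
      pr <- stats::predict(model$fit, df, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "HOMOLOG"])
    })
}

#' @export
print.homolog_classifier <- function(x, ...) {
  cat("homolog classifier (", x$learner, "), trained on ", x$n_train,
      " examples; features: ", paste(x$features, collapse = ", "),
      "; training accuracy ", sprintf("%.3f", x$train_accuracy), "\n",
      sep = "")
  invisible(x)
}

#' Classify one candidate pair
#'
#' @param model a `homolog_classifier`.
#' @param feature_vector named numeric vector from
#'   [compute_feature_vector()]; its feature set must match the model's.
#' @return list(is_homolog, probability). A probability exactly at the
#'   threshold classifies as homologous (>= convention).
#' @export
classify_pair <- function(model, feature_vector) {
  if (!setequal(names(feature_vector), model$features))
    stop("feature set mismatch: model uses [",
         paste(model$features, collapse = ", "), "], got [",
         paste(names(feature_vector), collapse = ", "), "]")
  p <- predict_homolog_prob(model, feature_vector[model$features])
  list(is_homolog = p >= model$threshold, probability = p)
}
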