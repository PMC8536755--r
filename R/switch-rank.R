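#' Random-forest configuration
#'
#' Defaults follow common practice for expression classifiers: 10,000 trees
#' and `mtry` equal to the square root of the feature count.
#'
#' @param n_trees Number of trees (>= 1).
#' @param mtry `"sqrt"` (floor of the square root of the number of genes) or
#'   an integer.
#' @param top_k_genes Size of the top-importance gene set used by the switch
#'   filter (default 25).
#' @param seed Integer seed.
#' @return Object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 10000, mtry = "sqrt", top_k_genes = 25,
                          seed = 1L) {
  if (n_trees < 1) abort("n_trees must be >= 1")
  if (top_k_genes < 1) abort("top_k_genes must be >= 1")
  structure(
    list(
      n_trees = as.integer(n_trees), mtry = mtry,
      top_k_genes = as.integer(top_k_genes), seed = as.integer(seed)
    ),
    class = "forest_config"
  )
}

resolve_mtry <- function(mtry, n_features) {
  if (identical(mtry, "sqrt")) max(1L, floor(sqrt(n_features))) else as.integer(mtry)
}

# Fits the backing tree ensemble and returns per-tree out-of-bag machinery:
# the fitted forest, the OOB indicator matrix and per-tree predictions for
# arbitrary feature tables.
fit_forest <- function(m, class_labels, config) {
  cl <- factor(class_labels)
  if (nlevels(cl) != 2) abort("exactly two classes are required")
  if (length(cl) != ncol(m)) abort("one class label per sample is required")
  xdf <- as.data.frame(t(m), check.names = FALSE)
  rf <- ranger::ranger(
    x = xdf, y = cl,
    num.trees = config$n_trees,
    mtry = resolve_mtry(config$mtry, nrow(m)),
    keep.inbag = TRUE, seed = config$seed, num.threads = 1
  )
  inbag <- simplify2array(rf$inbag.counts)
  list(
    rf = rf, xdf = xdf, y = cl,
    y_idx = match(as.character(cl), rf$forest$levels),
    oob = inbag == 0
  )
}

tree_accuracies <- function(fit, xdf) {
  preds <- stats::predict(fit$rf, data = xdf, predict.all = TRUE,
    num.threads = 1)$predictions
  hits <- preds == fit$y_idx
  hits[!fit$oob] <- NA
  colMeans(hits, na.rm = TRUE)
}

#' Gene importance by mean decrease in accuracy (MDA)
#'
#' Trains a bootstrap tree ensemble (ranger backend) on samples x genes and
#' computes, per gene, the permutation importance in-module: the gene's
#' values are permuted once (seeded) and the MDA is the mean over trees of
#' the drop in out-of-bag accuracy, `mean_t(acc_t - acc_t^perm)`. A single
#' shared permutation per gene (rather than one per tree) keeps the
#' contract testable independent of the backend; the estimator is unscaled.
#'
#' @param x Expression tibble or matrix (genes x samples).
#' @param class_labels Two-class vector, one label per sample.
#' @param config A [forest_config()].
#' @return Tibble with `gene_id`, `mda`, `rank` (descending by `mda`, ties
#'   broken by gene id).
#' @export
mda_importance <- function(x, class_labels, config = forest_config()) {
  m <- as_expr_matrix(x)
  fit <- fit_forest(m, class_labels, config)
  base_acc <- tree_accuracies(fit, fit$xdf)
  mda <- withr::with_seed(config$seed, {
    vapply(seq_len(nrow(m)), function(g) {
      xp <- fit$xdf
      xp[[g]] <- sample(xp[[g]])
      mean(base_acc - tree_accuracies(fit, xp), na.rm = TRUE)
    }, numeric(1))
  })
  tibble(gene_id = rownames(m), mda = mda) %>%
    arrange(desc(.data$mda), .data$gene_id) %>%
    mutate(rank = row_number())
}

#' Out-of-bag ROC evaluation of the forest classifier
#'
#' Scores each sample by its out-of-bag vote fraction for the positive class,
#' builds the ROC over all thresholds, integrates the AUC by the trapezoid
#' rule, and reports sensitivity/specificity at the Youden-optimal threshold
#' (maximising sensitivity + specificity - 1; ties resolved toward the
#' higher-sensitivity point). Samples with no OOB prediction are excluded.
#'
#' @inheritParams mda_importance
#' @param positive Positive-class label (default: first factor level).
#' @return Object of class `oob_eval`; see [glance.oob_eval()] and
#'   [tidy.oob_eval()].
#' @export
evaluate_oob <- function(x, class_labels, config = forest_config(),
                         positive = NULL) {
  m <- as_expr_matrix(x)
  fit <- fit_forest(m, class_labels, config)
  positive <- positive %||% levels(fit$y)[1]
  if (!positive %in% levels(fit$y)) abort("positive class not among labels")
  pos_idx <- match(positive, fit$rf$forest$levels)
  preds <- stats::predict(fit$rf, data = fit$xdf, predict.all = TRUE,
    num.threads = 1)$predictions
  is_pos_vote <- preds == pos_idx
  is_pos_vote[!fit$oob] <- NA
  n_oob_trees <- rowSums(fit$oob)
  keep <- n_oob_trees > 0
  score <- rowMeans(is_pos_vote, na.rm = TRUE)[keep]
  truth <- (as.character(fit$y) == positive)[keep]

  roc <- oob_roc(score, truth)
  youden <- roc$tpr + (1 - roc$fpr) - 1
  best <- which(youden == max(youden))
  best <- best[which.max(roc$tpr[best])]
  structure(
    list(
      auc = trapezoid_auc(roc$fpr, roc$tpr),
      sensitivity = roc$tpr[best],
      specificity = 1 - roc$fpr[best],
      threshold = roc$threshold[best],
      roc = roc,
      votes = tibble(
        sample_id = colnames(m)[keep], vote_fraction = score,
        class = as.character(fit$y)[keep]
      ),
      positive = positive,
      n_oob = sum(keep)
    ),
    class = "oob_eval"
  )
}

# ROC points over all distinct score thresholds (predict positive when
# score >= threshold), plus the two trivial endpoints.
oob_roc <- function(score, truth) {
  th <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(score[truth] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(score[!truth] >= t), numeric(1))
  tibble(
    threshold = c(Inf, th),
    tpr = c(0, tpr),
    fpr = c(0, fpr)
  )
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  x <- c(fpr[o], 1)
  y <- c(tpr[o], 1)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @rdname evaluate_oob
#' @param x An `oob_eval` object.
#' @param ... Unused.
#' @method glance oob_eval
#' @export
glance.oob_eval <- function(x, ...) {
  tibble(
    auc = x$auc, sensitivity = x$sensitivity, specificity = x$specificity,
    threshold = x$threshold, positive = x$positive, n_oob = x$n_oob
  )
}

#' @rdname evaluate_oob
#' @method tidy oob_eval
#' @export
tidy.oob_eval <- function(x, ...) x$roc

#' @export
print.oob_eval <- function(x, ...) {
  cat(sprintf(
    "Out-of-bag forest evaluation (positive class: %s)\n  AUC %.3f | sensitivity %.2f | specificity %.2f at vote threshold %.3f (n = %d)\n",
    x$positive, x$auc, x$sensitivity, x$specificity, x$threshold, x$n_oob
  ))
  invisible(x)
}

#' Filter triplets by switch-gene evidence
#'
#' Keeps triplets whose X3 gene is both among the `top_k` most important
#' genes of the forest ranking and flagged as a non-random X3 occupant.
#'
#' @param triplets Triplet tibble with `x3_id`.
#' @param importance Tibble from [mda_importance()].
#' @param flagged_x3 Character vector of flagged gene ids (e.g. the `gene_id`
#'   of flagged rows from [flag_nonrandom_x3()]).
#' @param top_k Importance cutoff (default 25).
#' @return The retained triplets, order preserved; a warning is emitted when
#'   the intersection is empty.
#' @export
filter_triplets_by_switch <- function(triplets, importance, flagged_x3,
                                      top_k = 25) {
  top <- importance$gene_id[importance$rank <= top_k]
  keep <- intersect(top, flagged_x3)
  if (length(keep) == 0) {
    warn("no gene is both top-ranked and non-randomly occupying X3; returning 0 triplets")
  }
  filter(triplets, .data$x3_id %in% keep)
}
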