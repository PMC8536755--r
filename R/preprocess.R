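#' Between-array quantile normalization
#'
#' Forces every sample column onto the same empirical distribution: each
#' column's sorted values are replaced by the row-wise mean of all columns'
#' sorted values (ties receive the average of the corresponding reference
#' values), preserving within-column rank order. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x Expression tibble (gene ids in column 1) or matrix.
#' @return Tibble of the same shape as the input.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 4, 6), ncol = 2,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' quantile_normalize(m) # both columns become 1.5, 3, 4.5
quantile_normalize <- function(x) {
  m <- as_expr_matrix(x)
  if (ncol(m) < 2) abort("quantile normalization needs at least 2 samples")
  if (anyNA(m)) abort("matrix has missing values; impute before normalizing")
  check_finite(m)
  out <- limma::normalizeQuantiles(m)
  dimnames(out) <- dimnames(m)
  expr_tibble(out)
}

#' Collapse duplicate probes to genes by interquartile range
#'
#' For each gene, keeps the probe with the largest IQR across samples (the
#' most variable, hence most informative, measurement); ties are broken by
#' the lexicographically smallest probe id. Probes absent from the map are
#' dropped as unannotated.
#'
#' @param x Probe-level expression tibble (probe ids in column 1) or matrix.
#' @param probe_map Data frame with columns `probe_id`, `gene_id`.
#' @return Expression tibble with one row per gene (`gene_id` first column).
#' @export
collapse_duplicates_iqr <- function(x, probe_map) {
  m <- as_expr_matrix(x)
  if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
    abort("probe_map needs columns 'probe_id' and 'gene_id'")
  }
  if (nrow(probe_map) == 0) abort("probe_map is empty")
  map <- distinct(as_tibble(probe_map), .data$probe_id, .data$gene_id)
  keep <- map %>%
    filter(.data$probe_id %in% rownames(m)) %>%
    mutate(iqr = apply(m[.data$probe_id, , drop = FALSE], 1, stats::IQR)) %>%
    arrange(.data$gene_id, desc(.data$iqr), .data$probe_id) %>%
    group_by(.data$gene_id) %>%
    slice_head(n = 1) %>%
    ungroup()
  out <- m[keep$probe_id, , drop = FALSE]
  rownames(out) <- keep$gene_id
  expr_tibble(out)
}

#' Empirical-Bayes moderated-t differential expression
#'
#' Fits, per gene, a two-class linear model and shrinks the residual
#' variances towards a common prior by empirical Bayes: the posterior
#' variance is `(d0*s0^2 + dg*sg^2) / (d0 + dg)`, with the prior degrees of
#' freedom `d0` and prior variance `s0^2` estimated by moment matching on the
#' log sample variances, and two-sided p-values from a t distribution with
#' `d0 + dg` degrees of freedom (delegated to [limma::eBayes()]). A BH FDR
#' column is included; the `significant` flag uses the *raw* moderated p at
#' `p_threshold`, with the FDR column reported alongside.
#'
#' @param x Expression tibble or matrix.
#' @param class_labels Vector of two class labels, one per sample (character
#'   or factor).
#' @param p_threshold Raw-p cutoff for the `significant` flag (default 0.01).
#' @return Tibble sorted by ascending p-value with columns `gene_id`,
#'   `log_fold_change`, `moderated_t`, `p_value`, `bh_fdr`, `significant`,
#'   and attributes `df_prior` (`d0`) and `s2_prior` (`s0^2`).
#' @export
moderated_t_deg <- function(x, class_labels, p_threshold = 0.01) {
  m <- as_expr_matrix(x)
  check_finite(m)
  cl <- factor(class_labels)
  if (nlevels(cl) != 2) abort("class_labels must contain exactly two classes")
  if (any(table(cl) < 2)) abort("each class needs at least 2 samples")
  if (length(cl) != ncol(m)) abort("one class label per sample is required")
  design <- stats::model.matrix(~cl)
  fit <- limma::eBayes(limma::lmFit(m, design))
  out <- tibble(
    gene_id = rownames(m),
    log_fold_change = unname(fit$coefficients[, 2]),
    moderated_t = unname(fit$t[, 2]),
    p_value = unname(fit$p.value[, 2]),
    bh_fdr = unname(bh_adjust(fit$p.value[, 2]))
  ) %>%
    mutate(significant = .data$p_value < p_threshold) %>%
    arrange(.data$p_value, .data$gene_id)
  attr(out, "df_prior") <- unname(fit$df.prior)
  attr(out, "s2_prior") <- unname(fit$s2.prior)
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the input order, each `>=` its raw p-value and
#'   `<= 1`, monotone after the step-up enforcement.
#' @export
#' @examples
#' bh_adjust(c(0.005, 0.01, 0.03, 0.04)) # 0.02 0.02 0.04 0.04
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1] and be non-missing")
  }
  p.adjust(p_values, method = "BH")
}
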