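#' Rank-based normal quantile transform
#'
#' Maps the value with rank `r` (average ranks for ties) to the standard
#' normal quantile `qnorm(r / (n + 1))`, giving an approximately normal
#' marginal while preserving order. Applied gene-wise before liquid
#' association scoring to damp outliers.
#'
#' @param x Numeric vector of length >= 3, not all values identical.
#' @return Transformed vector of the same length.
#' @export
#' @examples
#' normal_quantile_transform(c(5, 1, 9)) # 0, -0.6745, 0.6745
normal_quantile_transform <- function(x) {
  if (length(x) < 3) abort("need at least 3 values")
  if (anyNA(x)) abort("missing values are not allowed")
  if (max(x) == min(x)) abort("constant vector: ranks are undefined")
  qnorm(rank(x, ties.method = "average") / (length(x) + 1))
}

#' Standardize to mean 0, variance 1
#'
#' Centres and scales by the sample standard deviation (denominator `n - 1`).
#'
#' @param x Numeric vector with nonzero sample variance.
#' @return Standardized vector.
#' @export
standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("zero variance: cannot standardize")
  (x - mean(x)) / s
}

#' Liquid-association preprocessing transform
#'
#' The composition used before MLA scoring: normal quantile transform, then
#' standardization.
#'
#' @param x Numeric vector.
#' @return Transformed vector.
#' @export
la_transform <- function(x) standardize(normal_quantile_transform(x))

# Bin diagnostics shared by mla_score and the scan: contiguous near-equal
# bins over sorted x3 (stable ties), per-bin Pearson correlation of (x1, x2)
# with zero-variance bins contributing 0, and per-bin x3 means.
mla_details <- function(x1, x2, x3, bins) {
  n <- length(x3)
  if (length(x1) != n || length(x2) != n) abort("vectors must have equal length")
  if (bins < 3) abort("at least 3 bins are required")
  if (n < 3 * bins) {
    abort(sprintf("insufficient samples for %d bins: need n >= %d, got %d", bins, 3 * bins, n))
  }
  assign <- bin_assign(x3, bins)
  rho <- numeric(bins)
  x3_mean <- numeric(bins)
  n_bin <- integer(bins)
  for (i in seq_len(bins)) {
    idx <- which(assign == i)
    n_bin[i] <- length(idx)
    x3_mean[i] <- mean(x3[idx])
    if (sd(x1[idx]) == 0 || sd(x2[idx]) == 0) {
      rho[i] <- 0
    } else {
      rho[i] <- cor(x1[idx], x2[idx])
    }
  }
  list(
    score = sum(rho * x3_mean) / bins,
    bins = tibble(bin = seq_len(bins), n_samples = n_bin, rho = rho, x3_mean = x3_mean)
  )
}

#' Modified liquid-association (MLA) score
#'
#' Sorts samples by `x3`, splits them into `bins` contiguous near-equal bins
#' (sizes differing by at most one, larger bins at lower `x3`; ties broken by
#' sample index) and returns the mean over bins of the within-bin Pearson
#' correlation of `x1`, `x2` weighted by the bin's mean `x3`:
#' `sum_i rho_i * mean(x3_i) / M`. Inputs are expected to be already
#' [la_transform()]ed (normal quantile transform + standardization); bins in
#' which `x1` or `x2` is constant contribute a correlation of 0.
#'
#' @param x1,x2 The gene pair whose co-expression is probed.
#' @param x3 The candidate switch gene whose level defines the bins.
#' @param bins Number of bins `M` (>= 3, default 3).
#' @param details If `TRUE`, return a list with the score and a per-bin
#'   diagnostic tibble (`bin`, `n_samples`, `rho`, `x3_mean`).
#' @return Numeric score, or a list when `details = TRUE`.
#' @export
#' @examples
#' set.seed(1)
#' tri <- sample_switch_triplet(120, rho = 0.9)
#' mla_score(la_transform(tri$x1), la_transform(tri$x2), la_transform(tri$x3))
mla_score <- function(x1, x2, x3, bins = 3, details = FALSE) {
  d <- mla_details(x1, x2, x3, bins)
  if (details) d else d$score
}

#' Permutation p-value for an MLA score
#'
#' Builds the null by permuting `x3` against the fixed `(x1, x2)` pair and
#' recomputing the score; the two-sided p-value is
#' `(1 + #{|score_perm| >= |score_obs|}) / (n_perm + 1)`. Since sorting a
#' permuted `x3` yields the same per-bin value multisets, permutation is
#' realised as a random reassignment of samples to the fixed bins, which is
#' exact and fast.
#'
#' @inheritParams mla_score
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed (otherwise the current RNG state is
#'   used).
#' @return P-value in `[1/(n_perm + 1), 1]`.
#' @export
mla_pvalue <- function(x1, x2, x3, bins = 3, n_perm = 999, seed = NULL) {
  if (n_perm < 99) abort("n_perm must be at least 99")
  d <- mla_details(x1, x2, x3, bins)
  obs <- d$score
  run <- function() {
    n <- length(x3)
    sizes <- bin_sizes(n, bins)
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    m3 <- d$bins$x3_mean
    idx <- vapply(seq_len(n_perm), function(b) sample.int(n), integer(length(x3)))
    a1 <- matrix(x1[idx], nrow = length(x3))
    a2 <- matrix(x2[idx], nrow = length(x3))
    null_scores <- numeric(n_perm)
    for (i in seq_len(bins)) {
      r <- starts[i]:ends[i]
      b1 <- a1[r, , drop = FALSE]
      b2 <- a2[r, , drop = FALSE]
      mu1 <- colMeans(b1)
      mu2 <- colMeans(b2)
      num <- colMeans(b1 * b2) - mu1 * mu2
      den <- sqrt((colMeans(b1^2) - mu1^2) * (colMeans(b2^2) - mu2^2))
      rho <- ifelse(den > 0, num / den, 0)
      null_scores <- null_scores + rho * m3[i] / bins
    }
    (1 + sum(abs(null_scores) >= abs(obs))) / (n_perm + 1)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Parameters for the triplet scan
#'
#' @param bins Number of bins `M` over X3 (>= 3).
#' @param n_perm Permutations per candidate (>= 99 when
#'   `p_method = "permutation"`).
#' @param top_k Maximum number of retained triplets.
#' @param fdr_threshold BH FDR cut defining "statistically significant"
#'   triplets downstream.
#' @param p_method `"permutation"` (reference), `"normal"` (analytic
#'   approximation using the null variance `sum(mean(x3_i)^2 / (n_i - 1)) /
#'   M^2`, usable when FDR thresholds below any feasible permutation
#'   resolution are required), or `"none"` (scores only, ranking by
#'   absolute score).
#' @param seed Integer seed for the permutation null.
#' @return Object of class `mla_params`.
#' @export
mla_params <- function(bins = 3, n_perm = 199, top_k = 200000,
                       fdr_threshold = 0.001,
                       p_method = c("permutation", "normal", "none"),
                       seed = 1L) {
  p_method <- match.arg(p_method)
  if (bins < 3) abort("bins must be >= 3")
  if (top_k < 1) abort("top_k must be >= 1")
  if (p_method == "permutation" && n_perm < 99) abort("n_perm must be >= 99")
  structure(
    list(
      bins = as.integer(bins), n_perm = as.integer(n_perm),
      top_k = as.integer(top_k), fdr_threshold = fdr_threshold,
      p_method = p_method, seed = as.integer(seed)
    ),
    class = "mla_params"
  )
}

#' Scan all gene triplets for liquid association
#'
#' Scores every triplet formed by a candidate switch gene X3 and every
#' unordered pair of other genes, after gene-wise [la_transform()]. At most
#' `top_k` records are retained, ranked by ascending p-value, then descending
#' absolute score (then gene ids for a total order); the BH FDR is computed
#' over the retained set, mirroring a top-K screen. With
#' `p_method = "permutation"`, each candidate's permutation null is shared
#' across all pairs, so per-triplet exact permutation p-values cost only
#' `n_perm` extra correlation passes per candidate.
#'
#' @param x Expression tibble or matrix (genes x samples), typically already
#'   restricted to genes of interest (e.g. DE genes).
#' @param x3_candidates Character vector of candidate switch genes (default:
#'   all genes).
#' @param params An [mla_params()] object.
#' @return Tibble with columns `x1_id`, `x2_id`, `x3_id`, `mla`, `p_value`,
#'   `bh_fdr`, per-bin diagnostics `rho_bin<i>` and `x3_mean_bin<i>`, and
#'   attributes `n_scored` (triplets scored before retention) and
#'   `n_examined_genes`.
#' @export
scan_triplets <- function(x, x3_candidates = NULL, params = mla_params()) {
  m <- as_expr_matrix(x)
  check_finite(m)
  ids <- rownames(m)
  if (is.null(x3_candidates)) x3_candidates <- ids
  if (length(x3_candidates) == 0) abort("empty x3 candidate list")
  missing_ids <- setdiff(x3_candidates, ids)
  if (length(missing_ids) > 0) {
    abort(paste0("candidates not in matrix: ", paste(missing_ids, collapse = ", ")))
  }
  G <- nrow(m)
  n <- ncol(m)
  M <- params$bins
  if (G < 3) abort("need at least 3 genes to form a triplet")
  if (n < 3 * M) abort(sprintf("insufficient samples for %d bins", M))

  tm <- t(apply(m, 1, la_transform)) # genes x samples, transformed
  sizes <- bin_sizes(n, M)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  iu <- which(upper.tri(matrix(0, G, G)))
  ri <- row(matrix(0, G, G))[iu]
  ci <- col(matrix(0, G, G))[iu]

  run <- function() {
    acc <- NULL
    n_scored <- 0
    for (cand in x3_candidates) {
      c_idx <- match(cand, ids)
      x3 <- tm[c_idx, ]
      ord <- order(x3, seq_len(n))
      bin_cols <- lapply(seq_len(M), function(i) ord[starts[i]:ends[i]])
      m3 <- vapply(bin_cols, function(j) mean(x3[j]), numeric(1))
      cors <- lapply(bin_cols, function(j) {
        ci_mat <- suppressWarnings(cor(t(tm[, j, drop = FALSE])))
        ci_mat[!is.finite(ci_mat)] <- 0
        ci_mat
      })
      S <- Reduce(`+`, Map(`*`, cors, m3)) / M

      p_mat <- NULL
      if (params$p_method == "permutation") {
        cnt <- matrix(0, G, G)
        for (b in seq_len(params$n_perm)) {
          idx <- sample.int(n)
          Sb <- matrix(0, G, G)
          for (i in seq_len(M)) {
            j <- idx[starts[i]:ends[i]]
            cb <- suppressWarnings(cor(t(tm[, j, drop = FALSE])))
            cb[!is.finite(cb)] <- 0
            Sb <- Sb + cb * (m3[i] / M)
          }
          cnt <- cnt + (abs(Sb) >= abs(S))
        }
        p_mat <- (1 + cnt) / (params$n_perm + 1)
      } else if (params$p_method == "normal") {
        sd_null <- sqrt(sum(m3^2 / (sizes - 1))) / M
        p_mat <- 2 * pnorm(-abs(S) / sd_null)
      }

      ok <- ri != c_idx & ci != c_idx
      n_scored <- n_scored + sum(ok)
      rec <- tibble(
        x1_id = ids[ri[ok]], x2_id = ids[ci[ok]], x3_id = cand,
        mla = S[iu][ok],
        p_value = if (is.null(p_mat)) NA_real_ else p_mat[iu][ok]
      )
      for (i in seq_len(M)) {
        rec[[paste0("rho_bin", i)]] <- cors[[i]][iu][ok]
        rec[[paste0("x3_mean_bin", i)]] <- m3[i]
      }
      acc <- bind_rows(acc, rec)
      if (nrow(acc) > 2L * params$top_k) acc <- rank_truncate(acc, params$top_k)
    }
    out <- rank_truncate(acc, params$top_k)
    out$bh_fdr <- if (all(is.na(out$p_value))) NA_real_ else bh_adjust(out$p_value)
    out <- dplyr::relocate(out, "bh_fdr", .after = "p_value")
    attr(out, "n_scored") <- n_scored
    attr(out, "n_examined_genes") <- G
    out
  }
  if (params$p_method == "permutation") withr::with_seed(params$seed, run()) else run()
}

# Total-order retention: ascending p (NA last, i.e. score-only mode keeps
# every record comparable by |mla|), descending |mla|, then ids.
rank_truncate <- function(df, top_k) {
  df %>%
    arrange(.data$p_value, desc(abs(.data$mla)), .data$x3_id, .data$x1_id, .data$x2_id) %>%
    slice_head(n = top_k)
}
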