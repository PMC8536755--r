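#' Kruskal-Wallis rank test
#'
#' Tie-corrected rank-based H statistic with a chi-square reference on
#' `k - 1` degrees of freedom (delegated to [stats::kruskal.test()]). The
#' degenerate all-tied input, for which the tie correction is undefined, is
#' reported as `H = 0`, `p = 1` (no evidence of any group difference).
#'
#' @param values Numeric response vector.
#' @param group_labels Grouping vector (>= 2 non-empty groups).
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `n_groups`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3)) # H = 3.857
kruskal_wallis <- function(values, group_labels) {
  g <- as.factor(group_labels) # keeps explicitly declared (possibly empty) levels
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) == 0)) abort("every group needs at least one observation")
  if (length(values) != length(g)) abort("values and group_labels lengths differ")
  if (max(values) == min(values)) {
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1, n_groups = nlevels(g)))
  }
  kt <- stats::kruskal.test(values, g)
  tibble(
    statistic = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value, n_groups = nlevels(g)
  )
}

#' Clinic-pathological association of genes
#'
#' Kruskal-Wallis tests of each gene's expression across the groups of each
#' clinic-pathological feature. Continuous features are binned first: tumour
#' volume at `volume_cut` cm3 (below vs at/above), age at the sample median.
#' Each test additionally reports whether every group reaches
#' `min_group_size` samples; underpowered contrasts (e.g. very few large
#' tumours) are flagged rather than suppressed. Both raw and BH-adjusted
#' p-values (across all gene x feature tests) are reported.
#'
#' @param x Expression tibble or matrix.
#' @param metadata Sample metadata tibble (`sample_id`, `class`, `grade`,
#'   `volume_cm3`, `age`, `gender`, `recurrence`).
#' @param genes Genes to test (must exist in `x`).
#' @param features Metadata columns to test against (default all standard
#'   ones).
#' @param volume_cut Volume threshold in cm3 (default 20).
#' @param min_group_size Minimum per-group size for `adequate = TRUE`
#'   (default 5).
#' @return Tibble: `gene_id`, `feature`, `statistic`, `df`, `p_value`,
#'   `bh_fdr`, `group_sizes`, `adequate`.
#' @export
clinpath_association <- function(x, metadata, genes,
                                 features = c(
                                   "class", "grade", "volume_cm3", "age",
                                   "gender", "recurrence"
                                 ),
                                 volume_cut = 20, min_group_size = 5) {
  m <- as_expr_matrix(x)
  missing_genes <- setdiff(genes, rownames(m))
  if (length(missing_genes) > 0) {
    abort(paste0("unknown genes: ", paste(missing_genes, collapse = ", ")))
  }
  md <- as_tibble(metadata)
  if (!all(md$sample_id == colnames(m))) {
    m <- m[, md$sample_id, drop = FALSE]
  }
  group_of <- function(feature) {
    v <- md[[feature]]
    if (feature == "volume_cm3") {
      factor(ifelse(v >= volume_cut, paste0(">=", volume_cut), paste0("<", volume_cut)))
    } else if (feature == "age") {
      med <- median(v)
      factor(ifelse(v >= med, "older", "younger"))
    } else {
      factor(v)
    }
  }
  if (length(genes) == 0) {
    return(tibble(
      gene_id = character(), feature = character(), statistic = double(),
      df = double(), p_value = double(), bh_fdr = double(),
      group_sizes = character(), adequate = logical()
    ))
  }
  rows <- purrr::map(features, function(f) {
    grp <- group_of(f)
    purrr::map(genes, function(g) {
      if (nlevels(droplevels(grp)) < 2) {
        return(tibble(
          gene_id = g, feature = f, statistic = NA_real_, df = NA_real_,
          p_value = NA_real_, group_sizes = paste(table(droplevels(grp)), collapse = "/"),
          adequate = FALSE
        ))
      }
      kw <- kruskal_wallis(m[g, ], droplevels(grp))
      tibble(
        gene_id = g, feature = f, statistic = kw$statistic, df = kw$df,
        p_value = kw$p_value,
        group_sizes = paste(table(droplevels(grp)), collapse = "/"),
        adequate = all(table(droplevels(grp)) >= min_group_size)
      )
    })
  })
  out <- bind_rows(purrr::flatten(rows))
  ok <- !is.na(out$p_value)
  out$bh_fdr <- NA_real_
  out$bh_fdr[ok] <- bh_adjust(out$p_value[ok])
  dplyr::relocate(out, "bh_fdr", .after = "p_value")
}

#' Mean expression by class and grade, with a random-gene baseline
#'
#' Profiles each requested gene's mean expression per (class, grade) cell,
#' alongside an identically profiled baseline panel of
#' `ceiling(random_fraction * n_genes)` randomly drawn other genes (seeded),
#' mirroring the practice of benchmarking candidate marker genes against a
#' matched random fraction (about 0.1%) of the measured genome.
#'
#' @inheritParams clinpath_association
#' @param random_fraction Fraction of genes in the baseline panel
#'   (default 0.001).
#' @param seed Seed for the baseline draw.
#' @return Tibble of class `grade_profiles`: `gene_id`, `panel`
#'   (`"selected"` / `"random"`), `class`, `grade`, `mean_expression`,
#'   `n_samples`, plus `sem`.
#' @export
grade_profiles <- function(x, metadata, genes, random_fraction = 0.001,
                           seed = 1L) {
  m <- as_expr_matrix(x)
  missing_genes <- setdiff(genes, rownames(m))
  if (length(missing_genes) > 0) {
    abort(paste0("unknown genes: ", paste(missing_genes, collapse = ", ")))
  }
  md <- as_tibble(metadata)
  if (!all(md$sample_id == colnames(m))) m <- m[, md$sample_id, drop = FALSE]
  n_random <- ceiling(random_fraction * nrow(m))
  pool <- setdiff(rownames(m), genes)
  random_genes <- withr::with_seed(seed, sample(pool, min(n_random, length(pool))))
  panel <- tibble(
    gene_id = c(genes, random_genes),
    panel = rep(c("selected", "random"), c(length(genes), length(random_genes)))
  )
  cells <- md %>%
    mutate(.cell = paste(.data$class, .data$grade, sep = "|")) %>%
    group_by(.data$class, .data$grade, .data$.cell) %>%
    summarise(n_samples = n(), sample_ids = list(.data$sample_id), .groups = "drop")
  out <- tidyr::crossing(panel, cells) %>%
    mutate(
      mean_expression = purrr::map2_dbl(
        .data$gene_id, .data$sample_ids,
        function(g, s) mean(m[g, s])
      ),
      sem = purrr::map2_dbl(
        .data$gene_id, .data$sample_ids,
        function(g, s) if (length(s) > 1) sd(m[g, s]) / sqrt(length(s)) else NA_real_
      )
    ) %>%
    select("gene_id", "panel", "class", "grade", "mean_expression", "n_samples", "sem") %>%
    arrange(.data$panel, .data$gene_id, .data$class, .data$grade)
  class(out) <- c("grade_profiles", class(out))
  out
}
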