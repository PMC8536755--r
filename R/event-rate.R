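#' Observed vs random event rates of switch-gene occupancy
#'
#' A validity diagnostic for the triplet screen. At each significance
#' threshold, the *random* event rate is the number of significant triplets
#' divided by the number of examined genes, while the *observed* event rate
#' is the number of significant triplets divided by the number of distinct
#' genes actually occupying the X3 position. When a few genes occupy most X3
#' positions -- the biological expectation, since few genes control most
#' processes -- the observed rate rises well above the random rate.
#'
#' @param triplets Triplet tibble (needs `x3_id` and `p_value`).
#' @param thresholds Numeric vector of significance cutoffs (applied to
#'   `p_value` as `p <= threshold`).
#' @param n_examined_genes Total number of genes examined in the scan.
#' @return Tibble of class `event_rate_curve` with columns `threshold`,
#'   `n_significant`, `n_unique_x3`, `random_rate`, `observed_rate`
#'   (thresholds sorted descending; both rates 0 where nothing is
#'   significant).
#' @export
compute_event_rates <- function(triplets, thresholds, n_examined_genes) {
  if (nrow(triplets) == 0) abort("empty triplet list")
  if (length(thresholds) == 0) abort("empty threshold list")
  if (n_examined_genes < 1) abort("n_examined_genes must be >= 1")
  out <- tibble(threshold = sort(thresholds, decreasing = TRUE)) %>%
    mutate(
      n_significant = vapply(
        .data$threshold,
        function(th) sum(triplets$p_value <= th, na.rm = TRUE), numeric(1)
      ),
      n_unique_x3 = vapply(
        .data$threshold,
        function(th) length(unique(triplets$x3_id[
          !is.na(triplets$p_value) & triplets$p_value <= th
        ])), numeric(1)
      ),
      random_rate = .data$n_significant / n_examined_genes,
      observed_rate = ifelse(.data$n_unique_x3 > 0,
        .data$n_significant / .data$n_unique_x3, 0
      )
    )
  attr(out, "n_examined_genes") <- n_examined_genes
  class(out) <- c("event_rate_curve", class(out))
  out
}

#' Flag genes with non-random X3 occupancy
#'
#' Formalises "non-random observed rate in the X3 position" per gene: under
#' the null that X3 positions are drawn uniformly from the examined genes, a
#' gene's occupancy count among `T` significant triplets is
#' Binomial(`T`, `1/n_examined_genes`). A one-sided upper tail
#' `P(X >= k)` is computed per occupying gene, BH-corrected across the tested
#' genes, and genes with adjusted p below `alpha` are flagged.
#'
#' @param triplets Tibble of (already significance-filtered) triplets.
#' @param n_examined_genes Number of genes examined in the scan.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return Tibble with `gene_id`, `n_triplets`, `expected`, `p_value`,
#'   `bh_fdr`, `flagged`, sorted by ascending p.
#' @export
flag_nonrandom_x3 <- function(triplets, n_examined_genes, alpha = 0.05) {
  if (nrow(triplets) == 0) abort("empty triplet list")
  n_trip <- nrow(triplets)
  p0 <- 1 / n_examined_genes
  count(triplets, gene_id = .data$x3_id, name = "n_triplets") %>%
    mutate(
      expected = n_trip * p0,
      p_value = pbinom(.data$n_triplets - 1, n_trip, p0, lower.tail = FALSE),
      bh_fdr = bh_adjust(.data$p_value),
      flagged = .data$bh_fdr < alpha
    ) %>%
    arrange(.data$p_value, .data$gene_id)
}
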