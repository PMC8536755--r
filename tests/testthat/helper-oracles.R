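# Independent oracles used to cross-check the package's implementations.
# Each is written from the definition, deliberately avoiding the package's
# own code paths.

# Direct evaluation of the binned liquid-association statistic: order by x3,
# cut into M contiguous near-equal bins (larger bins first), average
# rho_i * mean(x3_i) over bins. Pearson correlation from raw sums.
oracle_mla <- function(x1, x2, x3, M) {
  n <- length(x3)
  ord <- order(x3, seq_len(n))
  base <- n %/% M
  rem <- n %% M
  sizes <- base + as.integer(seq_len(M) <= rem)
  stops <- cumsum(sizes)
  total <- 0
  for (i in seq_len(M)) {
    idx <- ord[(stops[i] - sizes[i] + 1):stops[i]]
    a <- x1[idx]
    b <- x2[idx]
    sa <- sqrt(sum((a - mean(a))^2))
    sb <- sqrt(sum((b - mean(b))^2))
    r <- if (sa == 0 || sb == 0) 0 else sum((a - mean(a)) * (b - mean(b))) / (sa * sb)
    total <- total + r * mean(x3[idx])
  }
  total / M
}

# Moment matching of a scaled F prior to observed log sample variances
# (prior df d0 and prior variance s0^2), solved with uniroot on the
# trigamma equation.
oracle_variance_prior <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (evar <= 0) {
    return(list(df_prior = Inf, s2_prior = exp(emean)))
  }
  f <- function(x) trigamma(x) - evar
  half_d0 <- uniroot(f, c(1e-8, 1e8), tol = 1e-12)$root
  d0 <- 2 * half_d0
  s0 <- exp(emean + digamma(half_d0) - log(half_d0))
  list(df_prior = d0, s2_prior = s0)
}

# Exhaustive right-tail hypergeometric by enumerating every possible draw of
# `q` genes from a universe of size `N` containing a term of size `m`.
oracle_hypergeom_tail <- function(k, m, N, q) {
  draws <- utils::combn(N, q)
  in_term <- draws <= m # first m universe elements form the term
  mean(colSums(in_term) >= k)
}

# Kruskal-Wallis H with tie correction, straight from the rank-sum formula.
oracle_kruskal <- function(values, groups) {
  g <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rs <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  h <- 12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Sorted canonical key of a triplet (pair is unordered).
triplet_key <- function(x1, x2, x3) {
  paste(pmin(x1, x2), pmax(x1, x2), x3)
}
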