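test_that("normal quantile transform maps ranks to normal quantiles", {
  expect_equal(
    normal_quantile_transform(c(5, 1, 9)),
    qnorm(c(2, 1, 3) / 4),
    tolerance = 1e-12
  )
  expect_equal(normal_quantile_transform(c(5, 1, 9))[1], 0)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  out <- normal_quantile_transform(x)
  expect_true(all(diff(out[order(x)]) >= 0))
  # tied values map identically (average ranks)
  expect_equal(out[2], out[4])
  expect_error(normal_quantile_transform(rep(1, 5)), "constant")
  expect_error(normal_quantile_transform(c(1, 2)), "at least 3")
})

test_that("standardization has the stated fixed points and invariances", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(50, 4, 3)
  s <- standardize(x)
  expect_equal(mean(s), 0, tolerance = 1e-14)
  expect_equal(var(s), 1, tolerance = 1e-14)
  expect_equal(standardize(s), s, tolerance = 1e-12)
  expect_equal(standardize(2.5 * x - 7), s, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "zero variance")
})

test_that("mla_score has the stated degenerate values", {
  set.seed(3)
  x3 <- la_transform(rnorm(30))
  x1 <- la_transform(rnorm(30))
  # x1 == x2: every bin correlation is 1, bin means of standardized x3
  # average to its global mean 0 (equal bin sizes)
  expect_equal(mla_score(x1, x1, x3, bins = 3), 0, tolerance = 1e-12)
  # constant cross-bin correlation factorizes to ~0 the same way
  d <- mla_score(x1, x1, x3, bins = 3, details = TRUE)
  expect_equal(sum(d$bins$x3_mean) / 3, 0, tolerance = 1e-12)
  expect_error(mla_score(x1, x1, x3, bins = 11), "insufficient")
  expect_error(mla_score(x1, x1, x3[-1], bins = 3), "equal length")
})

test_that("mla_score equals the direct formula evaluation on random triplets", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(30:120, 1)
    M <- sample(3:5, 1)
    x1 <- la_transform(rnorm(n))
    x2 <- la_transform(rnorm(n))
    x3 <- la_transform(rnorm(n))
    expect_equal(mla_score(x1, x2, x3, bins = M), oracle_mla(x1, x2, x3, M),
      tolerance = 1e-12
    )
  }
})

test_that("score is symmetric in the pair and antisymmetric in x3", {
  set.seed(12)
  n <- 60 # divisible by 3: negating x3 exactly reverses the bins
  x1 <- la_transform(rnorm(n))
  x2 <- la_transform(rnorm(n))
  x3 <- la_transform(rnorm(n))
  expect_equal(mla_score(x1, x2, x3), mla_score(x2, x1, x3), tolerance = 1e-14)
  expect_equal(mla_score(x1, x2, -x3), -mla_score(x1, x2, x3), tolerance = 1e-12)
})

test_that("stored bin diagnostics reproduce the score", {
  set.seed(31)
  d <- mla_score(
    la_transform(rnorm(50)), la_transform(rnorm(50)),
    la_transform(rnorm(50)),
    bins = 4, details = TRUE
  )
  expect_equal(sum(d$bins$rho * d$bins$x3_mean) / 4, d$score, tolerance = 1e-14)
  expect_true(all(abs(d$bins$rho) <= 1))
  expect_equal(sum(d$bins$n_samples), 50)
  expect_equal(d$bins$n_samples, c(13, 13, 12, 12)) # larger bins at low x3
})

test_that("permutation p-values are bounded and detect planted triplets", {
  set.seed(4)
  x1 <- la_transform(rnorm(40))
  x2 <- la_transform(rnorm(40))
  x3 <- la_transform(rnorm(40))
  p <- mla_pvalue(x1, x2, x3, n_perm = 199, seed = 1)
  expect_gte(p, 1 / 200)
  expect_lte(p, 1)
  expect_identical(p, mla_pvalue(x1, x2, x3, n_perm = 199, seed = 1))
  expect_error(mla_pvalue(x1, x2, x3, n_perm = 50), "99")

  hits <- 0
  for (s in 1:10) {
    set.seed(1000 + s)
    tri <- sample_switch_triplet(120, rho = 0.9)
    p <- mla_pvalue(la_transform(tri$x1), la_transform(tri$x2),
      la_transform(tri$x3),
      n_perm = 999, seed = s
    )
    if (p == 1 / 1000) hits <- hits + 1
  }
  expect_gte(hits, 9) # planted signal pins the permutation minimum
})

test_that("scan enumerates pair-by-candidate triplets and retains top_k", {
  set.seed(6)
  m <- matrix(rnorm(10 * 30), 10, 30,
    dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:30))
  )
  cand <- c("g01", "g02", "g03")
  sc <- scan_triplets(m, cand, mla_params(p_method = "none", top_k = 1000))
  expect_equal(attr(sc, "n_scored"), choose(9, 2) * 3)
  expect_equal(nrow(sc), 108)
  expect_false(any(sc$x3_id == sc$x1_id | sc$x3_id == sc$x2_id))

  top5 <- scan_triplets(m, cand, mla_params(p_method = "none", top_k = 5))
  expect_equal(nrow(top5), 5)
  expect_equal(top5$mla, sc$mla[order(-abs(sc$mla))][1:5], tolerance = 1e-12)

  # every retained record matches a direct call on its own vectors
  tm <- apply(m, 1, la_transform)
  for (i in seq_len(nrow(top5))) {
    expect_equal(
      top5$mla[i],
      mla_score(tm[, top5$x1_id[i]], tm[, top5$x2_id[i]], tm[, top5$x3_id[i]]),
      tolerance = 1e-12
    )
  }
  expect_error(scan_triplets(m, character(0)), "empty")
  expect_error(scan_triplets(m, "nope"), "not in matrix")
})

test_that("scan permutation p-values agree with the single-triplet routine's null", {
  set.seed(9)
  m <- matrix(rnorm(6 * 60), 6, 60,
    dimnames = list(paste0("g", 1:6), paste0("s", 1:60))
  )
  m[2, ] <- m[1, ] * 0.7 + rnorm(60, sd = 0.3) # a correlated pair
  sc <- scan_triplets(m, "g3", mla_params(n_perm = 999, top_k = 100, seed = 2))
  expect_true(all(sc$p_value >= 1 / 1000 & sc$p_value <= 1))
  expect_equal(sc$bh_fdr, bh_adjust(sc$p_value), tolerance = 1e-12)
  # independent recomputation for the top record
  top <- sc[1, ]
  tm <- apply(m, 1, la_transform)
  p_direct <- mla_pvalue(tm[, top$x1_id], tm[, top$x2_id], tm[, top$x3_id],
    n_perm = 999, seed = 7
  )
  expect_lt(abs(p_direct - top$p_value), 0.05)
})

test_that("planted triplets dominate the top of a genome-scale scan", {
  recovered <- numeric(3)
  for (s in 1:3) {
    cfg <- synthetic_config(
      n_samples = 120, n_invasive = 60, n_genes = 200,
      n_planted_triplets = 20, rho = 0.85, n_de_genes = 0, seed = 100 + s
    )
    d <- generate_dataset(cfg)
    sc <- scan_triplets(d$expression, params = mla_params(p_method = "none", top_k = 4000))
    top <- head(sc, ceiling(attr(sc, "n_scored") * 0.001))
    tr <- d$truth$planted_triplets
    recovered[s] <- mean(
      triplet_key(tr$x1_id, tr$x2_id, tr$x3_id) %in%
        triplet_key(top$x1_id, top$x2_id, top$x3_id)
    )
  }
  expect_gte(median(recovered), 0.8)
})
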