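toy_matrix <- function(values, ids = NULL, samples = NULL) {
  m <- values
  rownames(m) <- ids %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("quantile normalization matches the sorted-mean reference", {
  m <- toy_matrix(cbind(c(1, 2, 3), c(2, 4, 6)))
  qn <- la3switch:::as_expr_matrix(quantile_normalize(m))
  expect_equal(unname(qn[, 1]), c(1.5, 3, 4.5))
  expect_equal(unname(qn[, 2]), c(1.5, 3, 4.5))

  # rank order within columns preserved, shuffled input
  set.seed(1)
  m2 <- toy_matrix(matrix(rnorm(60), 10, 6))
  qn2 <- la3switch:::as_expr_matrix(quantile_normalize(m2))
  for (j in 1:6) expect_equal(order(qn2[, j]), order(m2[, j]))
  # post-condition: every column has identical sorted values
  sorted <- apply(qn2, 2, sort)
  expect_equal(max(abs(sorted - rowMeans(apply(m2, 2, sort)))), 0)
})

test_that("quantile normalization is idempotent and a fixed point on equal columns", {
  m <- toy_matrix(cbind(c(5, 1, 7), c(5, 1, 7)))
  expect_equal(
    la3switch:::as_expr_matrix(quantile_normalize(m)), m
  )
  set.seed(2)
  m2 <- toy_matrix(matrix(rnorm(50), 10, 5))
  once <- quantile_normalize(m2)
  twice <- quantile_normalize(once)
  expect_equal(as.data.frame(twice), as.data.frame(once), tolerance = 1e-12)
  expect_error(quantile_normalize(m2[, 1, drop = FALSE]), "2 samples")
  m2[1, 1] <- NA
  expect_error(quantile_normalize(m2), "impute")
})

test_that("IQR probe collapse keeps the most variable probe per gene", {
  m <- toy_matrix(
    rbind(
      c(0, 1, 2, 3), # IQR 1.5
      c(0, 2, 4, 6), # IQR 3 -> winner for geneA
      c(5, 5, 5, 5), # unique to geneB
      c(9, 9, 9, 9) # unmapped -> dropped
    ),
    ids = c("p1", "p2", "p3", "p4")
  )
  map <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    gene_id = c("geneA", "geneA", "geneB")
  )
  out <- collapse_duplicates_iqr(m, map)
  expect_setequal(out$gene_id, c("geneA", "geneB"))
  expect_equal(unlist(out[out$gene_id == "geneA", -1]), m["p2", ], ignore_attr = TRUE)
  expect_equal(unlist(out[out$gene_id == "geneB", -1]), m["p3", ], ignore_attr = TRUE)

  # tie broken by lexicographically smallest probe id
  mt <- toy_matrix(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4)), ids = c("pB", "pA"))
  mt["pB", ] <- mt["pB", ] + 10 # same IQR, different level
  tie <- collapse_duplicates_iqr(
    mt, tibble::tibble(probe_id = c("pA", "pB"), gene_id = "g")
  )
  expect_equal(unlist(tie[1, -1]), mt["pA", ], ignore_attr = TRUE)

  expect_error(collapse_duplicates_iqr(m, map[0, ]), "empty")
})

test_that("moderated t is zero for equal group means and shrinks zero variances", {
  m <- toy_matrix(matrix(rnorm(200), 20, 10))
  m[1, ] <- rep(c(1, 2, 3, 4, 5), 2) # identical values in both groups
  m[2, ] <- 7 # zero variance everywhere
  cls <- rep(c("a", "b"), each = 5)
  deg <- moderated_t_deg(m, cls)
  r1 <- deg[deg$gene_id == "g01", ]
  expect_equal(r1$moderated_t, 0)
  expect_equal(r1$p_value, 1)
  r2 <- deg[deg$gene_id == "g02", ]
  expect_true(is.finite(r2$p_value)) # shrinkage gives s2 > 0
  expect_error(moderated_t_deg(m, rep("a", 10)), "two classes")
  expect_error(moderated_t_deg(m, c(rep("a", 9), "b")), "at least 2")
})

test_that("planted DE genes are recovered at high power", {
  cfg <- synthetic_config(
    n_samples = 40, n_invasive = 20, n_genes = 1050,
    n_planted_triplets = 0, n_de_genes = 50, de_effect = 2, seed = 21
  )
  d <- generate_dataset(cfg)
  deg <- moderated_t_deg(d$expression, d$metadata$class)
  planted <- d$truth$de_genes$gene_id
  hit <- mean(deg$significant[match(planted, deg$gene_id)])
  expect_gte(hit, 0.9)
})

test_that("variance prior matches an independent moment-matching fit", {
  set.seed(5)
  gene_sd <- sqrt(rchisq(60, 4) / 4)
  m <- toy_matrix(matrix(rnorm(600), 60, 10) * gene_sd)
  cls <- rep(c("a", "b"), each = 5)
  deg <- moderated_t_deg(m, cls)
  s2 <- apply(m, 1, function(v) {
    sum(tapply(v, cls, function(g) sum((g - mean(g))^2))) / 8
  })
  oracle <- oracle_variance_prior(s2, df = 8)
  expect_equal(attr(deg, "df_prior"), oracle$df_prior, tolerance = 1e-6)
  expect_equal(attr(deg, "s2_prior"), oracle$s2_prior, tolerance = 1e-6)
})

test_that("BH adjustment reproduces the step-up arithmetic", {
  expect_equal(
    bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
    c(0.02, 0.02, 0.04, 0.04)
  )
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(8)
  p <- runif(200)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # monotone in the sorted order
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
})
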