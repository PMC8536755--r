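named_matrix <- function(rows, n) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), sprintf("s%03d", seq_len(n)))
  m
}

test_that("mutual information has its closed-form values", {
  set.seed(1)
  x <- rnorm(100)
  expect_equal(mutual_information(x, x, n_bins = 4), log(4), tolerance = 1e-12)
  expect_equal(mutual_information(x, x, n_bins = 5), log(5), tolerance = 1e-12)
  # symmetry, exactly
  y <- rnorm(100)
  expect_identical(mutual_information(x, y), mutual_information(y, x))
  # constant input convention
  expect_identical(mutual_information(rep(1, 100), y), 0)
  expect_error(mutual_information(x, y[-1]), "equal length")
  expect_error(mutual_information(x[1:5], y[1:5], n_bins = 4), "at least")
})

test_that("MI estimates track the Gaussian closed form and the null", {
  set.seed(2)
  n <- 5000
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(n)
  expect_equal(mutual_information(x, y), -0.5 * log(1 - 0.64), tolerance = 0.1)
  # independent uniforms: near zero at modest bin counts (plug-in bias
  # ~ (k-1)^2 / (2n) bounds the default-bin estimate)
  u <- runif(n)
  v <- runif(n)
  expect_lte(mutual_information(u, v, n_bins = 5), 0.02)
  expect_lte(mutual_information(u, v), 0.05)
})

test_that("DPI prunes the indirect edge of a data-processing chain", {
  set.seed(3)
  n <- 200
  x <- rnorm(n)
  y <- x + 0.5 * rnorm(n)
  z <- y + 0.5 * rnorm(n)
  net <- build_mi_network(
    named_matrix(list(X = x, Y = y, Z = z, W = rnorm(n), V = rnorm(n)), n),
    n_perm = 99, seed = 5
  )
  key <- paste(net$edges$gene_a, net$edges$gene_b)
  expect_true(all(c("X Y", "Y Z") %in% key))
  expect_false("X Z" %in% key)
  expect_true(net$n_edges_pre_dpi >= nrow(net$edges))
  g <- glance(net)
  expect_equal(g$n_nodes, 5)
  expect_identical(tidy(net), net$edges)
})

test_that("DPI never removes an edge that dominates all its triangles", {
  set.seed(4)
  n <- 300
  x <- rnorm(n)
  m <- named_matrix(list(
    A = x, B = x + 0.3 * rnorm(n), C = x + 0.8 * rnorm(n), D = rnorm(n)
  ), n)
  net <- build_mi_network(m, n_perm = 99, seed = 1)
  key <- paste(net$edges$gene_a, net$edges$gene_b)
  expect_true("A B" %in% key) # strongest edge of every triangle it joins
})

test_that("independent genes yield edges near the type-I rate", {
  set.seed(6)
  G <- 12
  m <- matrix(rnorm(G * 150), G, 150,
    dimnames = list(paste0("g", 1:G), paste0("s", 1:150))
  )
  net <- build_mi_network(m, p_cut = 0.05, n_perm = 99, seed = 2)
  expect_lte(net$n_edges_pre_dpi, 0.15 * choose(G, 2))
})

test_that("seeded network construction is reproducible", {
  set.seed(7)
  m <- matrix(rnorm(10 * 80), 10, 80,
    dimnames = list(paste0("g", 1:10), paste0("s", 1:80))
  )
  m[2, ] <- m[1, ] + 0.4 * rnorm(80)
  m[3, ] <- m[2, ] + 0.4 * rnorm(80)
  m[5, ] <- m[4, ] + 0.4 * rnorm(80)
  n1 <- build_mi_network(m, n_perm = 99, seed = 42)
  n2 <- build_mi_network(m, n_perm = 99, seed = 42)
  expect_identical(n1$edges, n2$edges)
  key <- paste(n1$edges$gene_a, n1$edges$gene_b)
  expect_true(all(c("g1 g2", "g2 g3", "g4 g5") %in% key))
})

test_that("path support enforces the intermediate-gene bound", {
  edges <- tibble::tibble(
    gene_a = c("x3", "x3", "a", "b", "c"),
    gene_b = c("x1", "a", "b", "c", "x2"),
    mi = 1, p_value = 0.001
  )
  net <- structure(
    list(
      nodes = c("x1", "x2", "x3", "a", "b", "c", "lonely"),
      edges = edges, n_edges_pre_dpi = 5,
      params = list()
    ),
    class = "gene_network"
  )
  tr <- tibble::tibble(x1_id = "x1", x2_id = "x2", x3_id = "x3")
  # x3-x1 direct; x3-x2 needs 3 intermediates (a, b, c) -> unsupported at 2
  res2 <- triplet_path_support(net, tr, max_intermediates = 2)
  expect_false(res2$supported)
  expect_equal(res2$path_x1, "x3->x1")
  res3 <- triplet_path_support(net, tr, max_intermediates = 3)
  expect_true(res3$supported)
  expect_equal(res3$path_x2, "x3->a->b->c->x2")
  # monotone in the bound
  expect_true(all(!res2$supported | res3$supported))
  # disconnected and absent genes are unsupported
  tr2 <- tibble::tibble(
    x1_id = c("lonely", "missing"), x2_id = c("x1", "x1"), x3_id = "x3"
  )
  res4 <- triplet_path_support(net, tr2)
  expect_false(any(res4$supported))
  # subnetwork of the supported triplet covers the witnessing paths
  sub <- triplet_subnetwork(net, res3)
  expect_setequal(attr(sub, "nodes"), c("x3", "x1", "a", "b", "c", "x2"))
  expect_equal(nrow(sub), 5)
})

test_that("network export writes edge lists and GraphML", {
  set.seed(8)
  m <- matrix(rnorm(5 * 60), 5, 60,
    dimnames = list(paste0("g", 1:5), paste0("s", 1:60))
  )
  m[2, ] <- m[1, ] + 0.3 * rnorm(60)
  net <- build_mi_network(m, n_perm = 99, seed = 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, tsv)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), nrow(net$edges))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml, format = "graphml")
  expect_gt(file.size(gml), 0)
})
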