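write_toy_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("GMT parsing handles descriptions, levels, duplicates and errors", {
  path <- write_toy_gmt(c(
    "GO:1\tspindle organization level=7\tg1\tg2\tg2\tg3",
    "GO:2\tmrna processing\tg4\tg5"
  ))
  ann <- read_gmt(path)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$level, c(7L, NA_integer_))
  expect_equal(ann$term_name[1], "spindle organization")
  expect_setequal(ann$genes[[1]], c("g1", "g2", "g3")) # deduplicated
  expect_setequal(ann$genes[[2]], c("g4", "g5"))

  bad <- write_toy_gmt(c("GO:1\tok\tg1", "GO:2\tempty term"))
  expect_error(read_gmt(bad), "line 2")
  dup <- write_toy_gmt(c("GO:1\ta\tg1", "GO:1\tb\tg2"))
  expect_error(read_gmt(dup), "duplicate")

  # round trip preserves the level token
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ann, out)
  expect_equal(as.data.frame(read_gmt(out)), as.data.frame(ann))
})

test_that("hypergeometric p matches the exhaustive draw enumeration", {
  # universe of 10, term of 5, query of 3, overlap 3: C(5,3)/C(10,3) = 10/120
  universe <- paste0("g", 1:10)
  ann <- tibble::tibble(
    term_id = "T", term_name = "t", level = NA_integer_,
    genes = list(paste0("g", 1:5))
  )
  res <- suppressWarnings(
    hypergeom_enrich(paste0("g", 1:3), ann, universe, p_cut = 1, fdr_cut = 2)
  )
  expect_equal(res$p_value, 10 / 120, tolerance = 1e-12)
  expect_equal(res$p_value, 0.0833, tolerance = 1e-3)

  # random small configurations against brute force
  set.seed(19)
  for (i in 1:25) {
    N <- sample(8:14, 1)
    m <- sample(2:(N - 2), 1)
    q <- sample(2:(N - 2), 1)
    universe <- paste0("u", seq_len(N))
    ann <- tibble::tibble(
      term_id = "T", term_name = "t", level = NA_integer_,
      genes = list(universe[seq_len(m)])
    )
    query <- sample(universe, q)
    res <- suppressWarnings(
      hypergeom_enrich(query, ann, universe, p_cut = 1.1, fdr_cut = 2)
    )
    k <- res$overlap_count
    expect_equal(res$p_value, oracle_hypergeom_tail(k, m, N, q), tolerance = 1e-10)
  }
})

test_that("degenerate overlaps behave as stated", {
  universe <- paste0("g", 1:10)
  ann <- tibble::tibble(
    term_id = c("T1", "T2"), term_name = c("a", "b"), level = NA_integer_,
    genes = list(paste0("g", 1:5), paste0("g", 6:8))
  )
  # zero overlap: right tail is 1 and never reported
  res <- suppressWarnings(
    hypergeom_enrich(paste0("g", 9:10), ann, universe)
  )
  expect_equal(nrow(res), 0)
  all_terms <- attr(res, "all_terms")
  expect_true(all(all_terms$p_value == 1))
  # query == universe saturates every term
  res2 <- suppressWarnings(
    hypergeom_enrich(universe, ann, universe, p_cut = 1.01, fdr_cut = 2)
  )
  expect_true(all(res2$overlap_count == res2$term_size))
  expect_true(all(res2$p_value == 1))
  expect_error(
    hypergeom_enrich(c("g1", "zz"), ann, universe),
    "zz"
  )
})

test_that("ontology-level filter drops shallow terms when metadata exists", {
  universe <- paste0("g", 1:40)
  ann <- tibble::tibble(
    term_id = c("DEEP", "SHALLOW"), term_name = c("d", "s"),
    level = c(8L, 3L),
    genes = list(paste0("g", 1:4), paste0("g", 1:4))
  )
  res <- hypergeom_enrich(paste0("g", 1:4), ann, universe,
    p_cut = 0.05, fdr_cut = 0.5, min_level = 6
  )
  expect_equal(res$term_id, "DEEP")
})

test_that("null queries enrich ~5% of terms at p<0.05", {
  set.seed(23)
  universe <- paste0("g", 1:200)
  ann <- tibble::tibble(
    term_id = paste0("T", 1:40), term_name = "t", level = NA_integer_,
    genes = purrr::map(1:40, ~ sample(universe, 12))
  )
  frac <- vapply(1:60, function(i) {
    q <- sample(universe, 25)
    res <- suppressWarnings(
      hypergeom_enrich(q, ann, universe, p_cut = 1.1, fdr_cut = 2)
    )
    mean(res$p_value < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.05), 0.02)
})

test_that("shared-term rule keeps only pairs inside one enriched term", {
  enr <- tibble::tibble(
    term_id = c("T1", "T2"), term_name = c("a", "b"), level = 8L,
    genes = list(c("x", "y", "q"), c("x", "z"))
  )
  tr <- tibble::tibble(
    x1_id = c("x", "x", "q"), x2_id = c("y", "z", "z"),
    x3_id = c("s1", "s2", "s3")
  )
  out <- shared_term_triplets(tr, enr)
  expect_equal(out$x3_id, c("s1", "s2"))
  expect_equal(out$shared_terms[[1]], "T1")
  expect_equal(out$shared_terms[[2]], "T2")
  # a pair sharing only a non-enriched term is dropped
  out2 <- shared_term_triplets(tr, enr[1, ])
  expect_equal(out2$x3_id, "s1")
  out3 <- shared_term_triplets(tr, enr[0, ])
  expect_equal(nrow(out3), 0)
})
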