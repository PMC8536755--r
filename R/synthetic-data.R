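#' Configuration for the synthetic two-class expression study
#'
#' Describes a synthetic gene-expression study shaped like a two-class
#' (invasive vs non-invasive) tumour profiling experiment: a log-scale
#' gene-by-sample matrix with planted switch triplets, planted differentially
#' expressed (DE) genes, and pure-noise genes, plus clinic-pathological
#' covariates (grade, tumour volume, age, gender, recurrence).
#'
#' A planted switch triplet is a triple (X1, X2, X3) in which X3 is standard
#' normal and, conditional on a sample's X3 tercile, (X1, X2) are bivariate
#' normal with correlation `+rho` in the top tercile, `0` in the middle and
#' `-rho` in the bottom; every marginal has unit variance, so X1 and X2 are
#' marginally uncorrelated with each other and with X3. This instantiates
#' directly the quantity the binned liquid-association statistic measures.
#' In linked mode the terciles are those of the switch gene's latent
#' component, with the class shift overlaid on the emitted values: the
#' switching activity is treated as class-independent regulatory activity
#' of the same gene.
#'
#' Extensions beyond the basic construction, all off by default:
#' * `pairs_per_switch` plants several X1-X2 pairs governed by one shared X3,
#'   so a switch gene can occupy the X3 position of several triplets (the
#'   situation the non-random-occupancy flag is designed to detect);
#' * `switch_de_effect` / `pair_de_effect` add a between-class mean shift (in
#'   SD units) to switch and pair genes ("linked mode"), so planted genes
#'   survive a DE filter and carry random-forest signal;
#' * `network_link` adds, per switch gene, two unshifted relay genes
#'   correlated with X3 and with the first pair's X1 (resp. X2), giving the
#'   mutual-information network a short X3-X1 / X3-X2 path;
#' * `recurrence_link` ties the recurrence covariate to the first switch
#'   gene's expression, exercising the Kruskal-Wallis stage.
#'
#' @param n_samples Total sample count (default 40, as in a 22 + 18 study).
#' @param n_invasive Number of invasive samples (default 22).
#' @param n_genes Total gene count.
#' @param n_planted_triplets Number of planted switch genes (each with
#'   `pairs_per_switch` X1-X2 pairs).
#' @param rho Conditional X1-X2 correlation magnitude in `[0, 1)`.
#' @param n_de_genes Number of additional pure DE genes.
#' @param de_effect Between-class mean shift of DE genes, in SD units.
#' @param grade_assignment Named list mapping class to allowed grades;
#'   default non-invasive I-III, invasive III-IV.
#' @param seed Integer seed; the full output is a deterministic function of
#'   the configuration.
#' @param pairs_per_switch X1-X2 pairs per planted switch gene.
#' @param switch_de_effect,pair_de_effect Class shifts (SD units) for switch
#'   and pair genes (linked mode; default 0).
#' @param network_link Logical; add relay genes (see above).
#' @param recurrence_link Logical; tie recurrence to the first switch gene.
#' @return Object of class `synthetic_config` (a validated list).
#' @export
#' @examples
#' cfg <- synthetic_config(n_genes = 100, n_planted_triplets = 2, seed = 1)
#' dat <- generate_dataset(cfg)
#' dim(dat$expression)
synthetic_config <- function(n_samples = 40, n_invasive = 22, n_genes = 5000,
                             n_planted_triplets = 20, rho = 0.85,
                             n_de_genes = 100, de_effect = 1.5,
                             grade_assignment = list(
                               non_invasive = c("I", "II", "III"),
                               invasive = c("III", "IV")
                             ),
                             seed = 1L,
                             pairs_per_switch = 1L,
                             switch_de_effect = 0, pair_de_effect = 0,
                             network_link = FALSE, recurrence_link = FALSE) {
  if (n_invasive > n_samples) abort("n_invasive must not exceed n_samples")
  if (n_samples < 9) abort("n_samples must be at least 9 (three terciles of >=3)")
  if (rho < 0 || rho >= 1) abort("rho must lie in [0, 1)")
  if (pairs_per_switch < 1) abort("pairs_per_switch must be >= 1")
  n_relay <- if (network_link) 2L * n_planted_triplets else 0L
  n_planted <- n_planted_triplets * (1L + 2L * pairs_per_switch) + n_relay
  if (n_planted + n_de_genes > n_genes) {
    abort(sprintf(
      "gene slots overflow: %d planted + %d DE genes exceed n_genes = %d",
      n_planted, n_de_genes, n_genes
    ))
  }
  if (!all(c("non_invasive", "invasive") %in% names(grade_assignment))) {
    abort("grade_assignment needs entries 'non_invasive' and 'invasive'")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), n_invasive = as.integer(n_invasive),
      n_genes = as.integer(n_genes),
      n_planted_triplets = as.integer(n_planted_triplets), rho = rho,
      n_de_genes = as.integer(n_de_genes), de_effect = de_effect,
      grade_assignment = grade_assignment, seed = as.integer(seed),
      pairs_per_switch = as.integer(pairs_per_switch),
      switch_de_effect = switch_de_effect, pair_de_effect = pair_de_effect,
      network_link = isTRUE(network_link),
      recurrence_link = isTRUE(recurrence_link)
    ),
    class = "synthetic_config"
  )
}

#' Draw one planted switch triplet
#'
#' Samples X3 standard normal and, conditional on each sample's empirical X3
#' tercile (near-equal contiguous thirds of the sorted values), a bivariate
#' normal (X1, X2) with correlation `+rho` (top tercile), `0` (middle) or
#' `-rho` (bottom). All marginals have unit variance and X1, X2 are marginally
#' uncorrelated with X3 and with each other.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param n_samples Number of samples (>= 9).
#' @param rho Conditional correlation magnitude in `[0, 1)`.
#' @return Tibble with columns `x1`, `x2`, `x3` (one row per sample).
#' @export
#' @examples
#' set.seed(7)
#' tri <- sample_switch_triplet(600, rho = 0.9)
#' cor(tri$x1, tri$x2) # near zero: the tercile signs cancel
sample_switch_triplet <- function(n_samples, rho) {
  if (rho < 0 || rho >= 1) abort("rho must lie in [0, 1)")
  if (n_samples < 9) abort("n_samples must be at least 9")
  blk <- switch_block(n_samples, rho, pairs = 1L)
  tibble(x1 = blk$pairs[, 1], x2 = blk$pairs[, 2], x3 = blk$x3)
}

# x3 plus `pairs` conditionally correlated (x1, x2) pairs sharing its
# terciles. `shift` (e.g. a class effect) is added to the emitted x3 *after*
# terciles are computed on the latent component: the switching activity is a
# class-independent property of the gene, with the DE effect overlaid. With
# moderate shifts the emitted and latent orderings agree closely, so binning
# by observed x3 still recovers the planted partition; crucially, no other
# class-linked gene can read the partition through the class axis, which
# would otherwise create echo triplets on every class proxy.
switch_block <- function(n, rho, pairs = 1L, shift = 0) {
  latent <- rnorm(n)
  x3 <- latent + shift
  terc <- bin_assign(latent, 3L)
  rho_t <- c(-rho, 0, rho)[terc]
  mat <- matrix(0, n, 2L * pairs)
  for (j in seq_len(pairs)) {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    mat[, 2L * j - 1L] <- z1
    mat[, 2L * j] <- rho_t * z1 + sqrt(1 - rho_t^2) * z2
  }
  list(x3 = x3, latent = latent, pairs = mat)
}

#' Generate a synthetic expression study
#'
#' Builds the gene-by-sample matrix, the sample metadata table and the
#' ground-truth record described by a [synthetic_config()]. Gene slots are
#' laid out as: switch genes and their pair genes (and relay genes when
#' `network_link = TRUE`), then DE genes, then i.i.d. standard-normal noise
#' genes. Class mean shifts split symmetrically (+effect/2 invasive,
#' -effect/2 non-invasive) so the overall mean stays centred.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `expression` (tibble, `gene_id` + one column per
#'   sample), `metadata` (tibble) and `truth` (list of class
#'   `synthetic_truth`: `planted_triplets`, `de_genes`, `relay_genes`,
#'   `seed`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  n <- cfg$n_samples
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n))
  cls <- rep(c("invasive", "non_invasive"), c(cfg$n_invasive, n - cfg$n_invasive))
  cls_sign <- ifelse(cls == "invasive", 0.5, -0.5)

  m <- matrix(0, cfg$n_genes, n, dimnames = list(gene_ids, sample_ids))
  slot <- 0L
  take <- function(k) {
    out <- slot + seq_len(k)
    slot <<- slot + k
    out
  }

  triplets <- list()
  relays <- list()
  x3_first <- NULL
  for (s in seq_len(cfg$n_planted_triplets)) {
    blk <- switch_block(n, cfg$rho, cfg$pairs_per_switch,
      shift = cfg$switch_de_effect * cls_sign
    )
    i3 <- take(1L)
    ipairs <- take(2L * cfg$pairs_per_switch)
    m[i3, ] <- blk$x3
    if (s == 1L) x3_first <- blk$x3
    for (j in seq_len(cfg$pairs_per_switch)) {
      i1 <- ipairs[2L * j - 1L]
      i2 <- ipairs[2L * j]
      m[i1, ] <- blk$pairs[, 2L * j - 1L] + cfg$pair_de_effect * cls_sign
      m[i2, ] <- blk$pairs[, 2L * j] + cfg$pair_de_effect * cls_sign
      triplets[[length(triplets) + 1L]] <- tibble(
        x1_id = gene_ids[i1], x2_id = gene_ids[i2], x3_id = gene_ids[i3],
        rho = cfg$rho, pair_index = j
      )
    }
    if (cfg$network_link) {
      # Relay genes tie x3 to the first pair's members through the *latent*
      # (unshifted) signals, so relays carry no class effect themselves.
      for (target in 1:2) {
        ir <- take(1L)
        partner_latent <- blk$pairs[, target]
        m[ir, ] <- 0.65 * blk$latent + 0.65 * partner_latent + 0.4 * rnorm(n)
        relays[[length(relays) + 1L]] <- tibble(
          relay_id = gene_ids[ir], x3_id = gene_ids[i3],
          partner_id = gene_ids[ipairs[target]]
        )
      }
    }
  }

  de <- tibble(gene_id = character(), effect = double())
  if (cfg$n_de_genes > 0) {
    ide <- take(cfg$n_de_genes)
    for (i in ide) m[i, ] <- rnorm(n) + cfg$de_effect * cls_sign
    de <- tibble(gene_id = gene_ids[ide], effect = cfg$de_effect)
  }

  if (slot < cfg$n_genes) {
    rest <- (slot + 1L):cfg$n_genes
    m[rest, ] <- rnorm(length(rest) * n)
  }

  grades <- character(n)
  for (k in c("invasive", "non_invasive")) {
    idx <- which(cls == k)
    grades[idx] <- sample(cfg$grade_assignment[[k]], length(idx), replace = TRUE)
  }
  volume <- round(exp(rnorm(n, mean = 2, sd = 0.7)), 1)
  age <- pmin(pmax(round(rnorm(n, 55, 12)), 18), 85)
  gender <- sample(c("F", "M"), n, replace = TRUE)
  if (cfg$recurrence_link && !is.null(x3_first)) {
    p_rec <- stats::plogis(-1 + 1.5 * x3_first)
  } else {
    p_rec <- rep(0.3, n)
  }
  recurrence <- ifelse(runif(n) < p_rec, "yes", "no")

  metadata <- tibble(
    sample_id = sample_ids, class = cls, grade = grades,
    volume_cm3 = volume, age = age, gender = gender, recurrence = recurrence
  )
  truth <- structure(
    list(
      planted_triplets = bind_rows(triplets),
      de_genes = de,
      relay_genes = bind_rows(relays),
      seed = cfg$seed
    ),
    class = "synthetic_truth"
  )
  list(expression = expr_tibble(m), metadata = metadata, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Writes `expression.tsv` (rows = genes, first column `gene_id`, header row
#' of sample ids), `metadata.tsv` and `truth.json` into `out_dir`. Values
#' round-trip exactly through [read_dataset()].
#'
#' @param dataset List as returned by [generate_dataset()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_dataset <- function(dataset, out_dir) {
  expr <- dataset$expression
  if (is.null(expr) || nrow(expr) == 0 || ncol(expr) < 2) {
    abort("empty expression matrix: nothing to write")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(out_dir, "expression.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  readr::write_tsv(expr, paths[["expression"]])
  readr::write_tsv(dataset$metadata, paths[["metadata"]])
  tr <- dataset$truth
  jsonlite::write_json(
    list(
      planted_triplets = tr$planted_triplets, de_genes = tr$de_genes,
      relay_genes = tr$relay_genes, seed = tr$seed
    ),
    paths[["truth"]],
    dataframe = "columns", auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(paths)
}

#' Read a synthetic dataset back from disk
#'
#' @param dir Directory previously populated by [write_dataset()].
#' @return List with `expression`, `metadata`, `truth` as in
#'   [generate_dataset()].
#' @export
read_dataset <- function(dir) {
  expr <- readr::read_tsv(file.path(dir, "expression.tsv"),
    show_col_types = FALSE
  )
  metadata <- readr::read_tsv(file.path(dir, "metadata.tsv"),
    show_col_types = FALSE
  )
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  empty_df <- function(x, proto) if (length(x) == 0) proto else as_tibble(x)
  truth <- structure(
    list(
      planted_triplets = empty_df(tr$planted_triplets, tibble(
        x1_id = character(), x2_id = character(), x3_id = character(),
        rho = double(), pair_index = integer()
      )),
      de_genes = empty_df(tr$de_genes, tibble(gene_id = character(), effect = double())),
      relay_genes = empty_df(tr$relay_genes, tibble(
        relay_id = character(), x3_id = character(), partner_id = character()
      )),
      seed = tr$seed
    ),
    class = "synthetic_truth"
  )
  list(expression = expr, metadata = metadata, truth = truth)
}

#' Simulate a confirmatory switch-gene study
#'
#' A fixed, seeded study design used to exercise the whole pipeline: two
#' planted switch genes, each governing eight X1-X2 pairs (conditional
#' correlation 0.9 keyed to the switch gene's latent, class-independent
#' component), with class-linked expression (switch genes shifted by 1.15
#' SD, pair genes by 1 SD between classes), 12 additional DE genes (1 SD),
#' relay genes linking each switch gene to its first pair in the
#' mutual-information network, and noise genes up to 300 in total over 160
#' samples (88 invasive / 72 non-invasive, the 22:18 class ratio of a
#' typical invasiveness study at four times the size, giving the planted
#' triplets comfortable significance margins). The class shifts are kept
#' moderate deliberately: every class-linked gene weakly orders every other
#' through the class axis, so strong shifts would let class proxies echo the
#' planted switch structure as spurious significant triplets.
#'
#' The accompanying annotation table marks exactly the *first* pair of each
#' switch gene as functionally coherent: one term per switch gene containing
#' that pair plus the other switch gene (ontology level 8; the third member
#' keeps the term enrichable without admitting any other co-switched pair),
#' twenty 5-gene decoy terms over noise genes (level 7), and one broad
#' low-level term (level 3) that the ontology-level filter should exclude.
#' Run through the full pipeline, the design has exactly two confirmable
#' triplets: each switch gene yields several significant triplets (making
#' its X3 occupancy non-random), but only the annotated, relay-linked first
#' pairs can pass both the shared-term and the network path-support gates.
#'
#' @param seed Integer seed.
#' @return List with `expression`, `metadata`, `truth`, `annotations` (tibble
#'   as from [read_gmt()]), `config`, and `expected_confirmed` (tibble of the
#'   two triplets the pipeline should confirm).
#' @export
simulate_confirmatory_study <- function(seed = 1L) {
  cfg <- synthetic_config(
    n_samples = 160, n_invasive = 88, n_genes = 300,
    n_planted_triplets = 2, rho = 0.9, pairs_per_switch = 8,
    switch_de_effect = 1.15, pair_de_effect = 1,
    n_de_genes = 12, de_effect = 1,
    network_link = TRUE, recurrence_link = TRUE, seed = seed
  )
  dat <- generate_dataset(cfg)
  tr <- dat$truth$planted_triplets
  first <- dplyr::filter(tr, .data$pair_index == 1L)

  planted_ids <- unique(c(tr$x1_id, tr$x2_id, tr$x3_id, dat$truth$relay_genes$relay_id,
    dat$truth$de_genes$gene_id))
  noise_ids <- setdiff(dat$expression$gene_id, planted_ids)
  terms <- list()
  for (i in seq_len(nrow(first))) {
    # The term holds the annotated pair plus the *other* switch gene: a
    # third member that is essentially always in the enrichment query (it
    # heads several significant triplets itself) yet can never complete a
    # liquid-associated pair with either annotated gene. Deliberately *not*
    # the triplet's own switch gene -- a term containing X3 would let
    # rotated triplets (pair member in the X3 position) pass the
    # shared-term gate.
    other_x3 <- first$x3_id[if (i == 1L) nrow(first) else i - 1L]
    terms[[length(terms) + 1L]] <- tibble(
      term_id = sprintf("T:SWITCH%d", i),
      term_name = sprintf("coherent process of switch %d", i),
      level = 8L,
      genes = list(c(first$x1_id[i], first$x2_id[i], other_x3))
    )
  }
  decoy_pool <- withr::with_seed(seed + 1000L, sample(noise_ids))
  for (d in seq_len(20)) {
    terms[[length(terms) + 1L]] <- tibble(
      term_id = sprintf("T:DECOY%02d", d),
      term_name = sprintf("decoy process %d", d),
      level = 7L,
      genes = list(decoy_pool[(5 * (d - 1) + 1):(5 * d)])
    )
  }
  terms[[length(terms) + 1L]] <- tibble(
    term_id = "T:BROAD", term_name = "broad shallow term", level = 3L,
    genes = list(c(first$x1_id, first$x2_id, decoy_pool[101:140]))
  )
  annotations <- bind_rows(terms)

  list(
    expression = dat$expression, metadata = dat$metadata, truth = dat$truth,
    annotations = annotations, config = cfg,
    expected_confirmed = dplyr::select(first, "x1_id", "x2_id", "x3_id")
  )
}

#' Pipeline configuration matched to the confirmatory study
#'
#' The stage parameters under which [simulate_confirmatory_study()] is
#' designed to confirm exactly its two annotated, relay-linked triplets:
#' analytic-normal triplet p-values (the BH FDR gate at 0.001 is far below
#' any feasible permutation resolution), top-300 retention, a 1000-tree
#' forest with the importance gate at the top 40 of the roughly 55 DE genes,
#' and default enrichment/network cuts.
#'
#' @param study A [simulate_confirmatory_study()] result.
#' @param out_dir Output directory.
#' @param seed Global pipeline seed (defaults to the study's seed).
#' @return A [pipeline_config()].
#' @export
confirmatory_pipeline_config <- function(study, out_dir, seed = study$config$seed) {
  pipeline_config(
    expression = study$expression, metadata = study$metadata,
    annotations = study$annotations, out_dir = out_dir,
    mla = mla_params(p_method = "normal", top_k = 300, fdr_threshold = 0.001),
    forest = forest_config(n_trees = 1000, top_k_genes = 40, seed = seed),
    seed = seed
  )
}
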