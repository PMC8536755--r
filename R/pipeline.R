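#' Pipeline configuration
#'
#' Bundles the inputs and every stage's parameters for [run_pipeline()].
#' Inputs may be given as file paths (TSV for expression/metadata/probe map,
#' GMT for annotations) or as in-memory tibbles.
#'
#' @param expression Expression TSV path or tibble (gene ids in column 1).
#' @param metadata Metadata TSV path or tibble (`sample_id`, `class`,
#'   `grade`, `volume_cm3`, `age`, `gender`, `recurrence`).
#' @param out_dir Output directory for stage tables and the manifest.
#' @param probe_map Optional probe-to-gene TSV path or tibble (`probe_id`,
#'   `gene_id`); when given, duplicate probes are collapsed by IQR.
#' @param annotations Optional GMT path or annotation tibble; without it the
#'   enrichment and shared-term stages are skipped.
#' @param normalize Apply between-array quantile normalization (default
#'   `TRUE`).
#' @param deg_p Raw moderated-p threshold for the DE gene filter
#'   (default 0.01).
#' @param mla An [mla_params()] object.
#' @param event_thresholds Significance thresholds of the event-rate curve.
#' @param event_alpha BH level of the non-random-X3 flag (default 0.05).
#' @param forest A [forest_config()] object.
#' @param enrich_p,enrich_fdr,enrich_min_level Enrichment cutoffs
#'   (defaults 0.05, 0.1, 6).
#' @param enrich_universe `"all"` (all preprocessed genes, default) or
#'   `"degs"`.
#' @param grn_genes `"all"` (default) or `"degs"`: the gene set the MI
#'   network is built on. `"all"` lets regulatory paths traverse genes
#'   outside the triplets.
#' @param grn_p,grn_perm,grn_dpi_tolerance,grn_bins MI-network parameters.
#' @param max_intermediates Path-support bound (default 2).
#' @param clin_random_fraction Random baseline fraction for grade profiles
#'   (default 0.001).
#' @param clin_volume_cut,clin_min_group_size Clinical binning parameters.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, metadata, out_dir,
                            probe_map = NULL, annotations = NULL,
                            normalize = TRUE, deg_p = 0.01,
                            mla = mla_params(),
                            event_thresholds = 10^c(-10, -8, -6, -5, -4, -3, -2, log10(0.05)),
                            event_alpha = 0.05,
                            forest = forest_config(),
                            enrich_p = 0.05, enrich_fdr = 0.1,
                            enrich_min_level = 6,
                            enrich_universe = c("all", "degs"),
                            grn_genes = c("all", "degs"),
                            grn_p = 0.05, grn_perm = 99,
                            grn_dpi_tolerance = 0.1, grn_bins = NULL,
                            max_intermediates = 2,
                            clin_random_fraction = 0.001,
                            clin_volume_cut = 20, clin_min_group_size = 5,
                            seed = 1L) {
  for (p in list(expression, metadata, probe_map, annotations)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p)) {
      abort(paste0("input file does not exist: ", p))
    }
  }
  stopifnot(inherits(mla, "mla_params"), inherits(forest, "forest_config"))
  structure(
    list(
      expression = expression, metadata = metadata, out_dir = out_dir,
      probe_map = probe_map, annotations = annotations,
      normalize = isTRUE(normalize), deg_p = deg_p, mla = mla,
      event_thresholds = sort(event_thresholds, decreasing = TRUE),
      event_alpha = event_alpha, forest = forest,
      enrich_p = enrich_p, enrich_fdr = enrich_fdr,
      enrich_min_level = enrich_min_level,
      enrich_universe = match.arg(enrich_universe),
      grn_genes = match.arg(grn_genes), grn_p = grn_p, grn_perm = grn_perm,
      grn_dpi_tolerance = grn_dpi_tolerance, grn_bins = grn_bins,
      max_intermediates = max_intermediates,
      clin_random_fraction = clin_random_fraction,
      clin_volume_cut = clin_volume_cut,
      clin_min_group_size = clin_min_group_size,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' Only path-based inputs serialize; in-memory tibbles cannot be stored in a
#' config file.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- unclass(config)
  for (fld in c("expression", "metadata", "probe_map", "annotations")) {
    if (!is.null(flat[[fld]]) && !is.character(flat[[fld]])) {
      abort(paste0("cannot serialize in-memory input '", fld, "' to YAML"))
    }
  }
  flat$mla <- unclass(flat$mla)
  flat$forest <- unclass(flat$forest)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$mla <- do.call(mla_params, y$mla)
  y$forest <- do.call(forest_config, y$forest)
  y$event_thresholds <- as.numeric(y$event_thresholds)
  do.call(pipeline_config, y)
}

load_table <- function(x) {
  if (is.character(x) && length(x) == 1) {
    readr::read_tsv(x, show_col_types = FALSE)
  } else {
    as_tibble(x)
  }
}

load_annotations <- function(x) {
  if (is.null(x)) NULL else if (is.character(x) && length(x) == 1) read_gmt(x) else as_tibble(x)
}

# Stringify list-columns so every stage table writes as plain TSV.
write_stage <- function(df, out_dir, name) {
  flat <- df
  for (cl in names(flat)) {
    if (is.list(flat[[cl]])) {
      flat[[cl]] <- purrr::map_chr(flat[[cl]], paste, collapse = ";")
    }
  }
  readr::write_tsv(as_tibble(flat), file.path(out_dir, paste0(name, ".tsv")))
  df
}

#' Run the full switch-gene discovery pipeline
#'
#' Executes, in order: preprocessing (optional quantile normalization and
#' probe collapse, then the moderated-t DE filter), the MLA triplet scan over
#' the DE genes, the significance gate (BH FDR below the configured
#' threshold) with the event-rate diagnostic and the non-random-X3 flag, the
#' random-forest stage (MDA importance, OOB ROC, top-k intersection with the
#' flagged switch genes), gene-set enrichment with the shared-term rule, the
#' MI network with triplet path support, and finally the clinic-pathological
#' association of the confirmed switch genes. *Confirmed* triplets are those
#' passing both the shared-term and the path-support gates.
#'
#' Every stage's table is written to `out_dir` as TSV as soon as it is
#' produced (so partial output survives a failing later stage), along with a
#' `manifest.json` recording versions, seed and thresholds. Outputs are a
#' deterministic function of the configuration.
#'
#' @param config A [pipeline_config()].
#' @return List of class `la3_pipeline` with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  # -- preprocess ----------------------------------------------------------
  expr <- stage("load", {
    e <- load_table(config$expression)
    md <- load_table(config$metadata)
    if (!is.null(config$probe_map)) {
      e <- collapse_duplicates_iqr(e, load_table(config$probe_map))
    }
    if (config$normalize) e <- quantile_normalize(e)
    list(expression = e, metadata = md)
  })
  metadata <- expr$metadata
  expr <- expr$expression
  classes <- metadata$class[match(colnames(as_expr_matrix(expr)), metadata$sample_id)]

  deg <- stage("deg", moderated_t_deg(expr, classes, config$deg_p))
  write_stage(deg, out_dir, "degs")
  deg_genes <- deg$gene_id[deg$significant]
  if (length(deg_genes) < 3) abort("fewer than 3 DE genes; nothing to scan")
  m_all <- as_expr_matrix(expr)
  m_deg <- m_all[deg_genes, , drop = FALSE]

  # -- triplet scan and significance gate ---------------------------------
  triplets <- stage("scan", scan_triplets(m_deg, params = config$mla))
  write_stage(triplets, out_dir, "triplets")
  n_examined <- attr(triplets, "n_examined_genes")
  if (nrow(triplets) == config$mla$top_k &&
    sum(triplets$bh_fdr < config$mla$fdr_threshold, na.rm = TRUE) == nrow(triplets)) {
    warn("top_k is below the significant-triplet count; downstream stages use the retained set")
  }
  significant <- filter(triplets, .data$bh_fdr < config$mla$fdr_threshold)
  write_stage(significant, out_dir, "significant_triplets")
  if (nrow(significant) == 0) abort("no significant triplets at the configured FDR")

  event_curve <- stage("event_rate", compute_event_rates(
    triplets, config$event_thresholds, n_examined
  ))
  write_stage(event_curve, out_dir, "event_rates")
  flags <- stage("event_rate", flag_nonrandom_x3(
    significant, n_examined, config$event_alpha
  ))
  write_stage(flags, out_dir, "x3_flags")

  # -- random-forest switch ranking ---------------------------------------
  fc <- config$forest
  fc$seed <- config$seed + 1L
  importance <- stage("switch_rank", mda_importance(m_deg, classes, fc))
  write_stage(importance, out_dir, "importance")
  oob <- stage("switch_rank", evaluate_oob(m_deg, classes, fc, positive = "invasive"))
  write_stage(glance(oob), out_dir, "oob_eval")
  filtered <- stage("switch_rank", filter_triplets_by_switch(
    significant, importance, flags$gene_id[flags$flagged], fc$top_k_genes
  ))
  write_stage(filtered, out_dir, "switch_filtered")

  # -- enrichment and shared-term gate ------------------------------------
  annotations <- load_annotations(config$annotations)
  if (!is.null(annotations)) {
    query <- unique(c(significant$x1_id, significant$x2_id, significant$x3_id))
    universe <- if (config$enrich_universe == "all") rownames(m_all) else deg_genes
    enriched <- stage("enrichment", hypergeom_enrich(
      query, annotations, universe,
      p_cut = config$enrich_p, fdr_cut = config$enrich_fdr,
      min_level = config$enrich_min_level
    ))
    write_stage(select(enriched, -"genes"), out_dir, "enrichment")
    shared <- stage("enrichment", shared_term_triplets(filtered, enriched))
  } else {
    enriched <- NULL
    shared <- mutate(filtered,
      shared_terms = list(character(0)),
      shared_terms_str = ""
    )[0, ]
  }
  write_stage(shared, out_dir, "shared_term_triplets")

  # -- regulatory network and path-support gate ---------------------------
  grn_matrix <- if (config$grn_genes == "all") m_all else m_deg
  network <- stage("grn", build_mi_network(
    grn_matrix,
    p_cut = config$grn_p, n_perm = config$grn_perm,
    dpi_tolerance = config$grn_dpi_tolerance, n_bins = config$grn_bins,
    seed = config$seed + 2L
  ))
  write_stage(network$edges, out_dir, "network_edges")
  support <- stage("grn", triplet_path_support(
    network, filtered, config$max_intermediates
  ))
  write_stage(support, out_dir, "path_support")

  confirmed <- stage("confirm", {
    keys <- c("x1_id", "x2_id", "x3_id")
    semi_join(shared, filter(support, .data$supported), by = keys)
  })
  write_stage(confirmed, out_dir, "confirmed_triplets")

  # -- clinic-pathological association ------------------------------------
  switch_genes <- unique(confirmed$x3_id)
  if (length(switch_genes) > 0) {
    clin <- stage("clinpath", clinpath_association(
      m_all, metadata, switch_genes,
      volume_cut = config$clin_volume_cut,
      min_group_size = config$clin_min_group_size
    ))
    profiles <- stage("clinpath", grade_profiles(
      m_all, metadata, switch_genes,
      random_fraction = config$clin_random_fraction,
      seed = config$seed + 3L
    ))
  } else {
    clin <- clinpath_association(m_all, metadata, character(0))
    profiles <- grade_profiles(m_all, metadata,
      rownames(m_all)[1],
      random_fraction = 0, seed = config$seed + 3L
    )[0, ]
  }
  write_stage(clin, out_dir, "clinpath")
  write_stage(profiles, out_dir, "grade_profiles")

  manifest <- list(
    package = "la3switch",
    package_version = as.character(utils::packageVersion("la3switch")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = list(
      deg_p = config$deg_p, mla_fdr = config$mla$fdr_threshold,
      mla_bins = config$mla$bins, mla_p_method = config$mla$p_method,
      event_alpha = config$event_alpha,
      forest_top_k = config$forest$top_k_genes,
      enrich_p = config$enrich_p, enrich_fdr = config$enrich_fdr,
      grn_p = config$grn_p, max_intermediates = config$max_intermediates
    ),
    n_genes = nrow(m_all), n_samples = ncol(m_all),
    n_deg = length(deg_genes),
    n_significant_triplets = nrow(significant),
    n_confirmed_triplets = nrow(confirmed)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  structure(
    list(
      deg = deg, triplets = triplets, significant = significant,
      event_curve = event_curve, x3_flags = flags,
      importance = importance, oob = oob, switch_filtered = filtered,
      enrichment = enriched, shared = shared, network = network,
      path_support = support, confirmed = confirmed,
      clinpath = clin, grade_profiles = profiles,
      manifest = manifest, config = config
    ),
    class = "la3_pipeline"
  )
}

#' @export
print.la3_pipeline <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Switch-gene discovery run (seed %d)\n",
      "  DE genes: %d | significant triplets: %d | switch-filtered: %d\n",
      "  shared-term: %d | network-supported: %d | confirmed: %d\n"
    ),
    x$config$seed, sum(x$deg$significant), nrow(x$significant),
    nrow(x$switch_filtered), nrow(x$shared), sum(x$path_support$supported),
    nrow(x$confirmed)
  ))
  invisible(x)
}
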