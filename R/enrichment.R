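#' Read a GMT gene-set file
#'
#' One tab-separated record per line: `term_id<TAB>description<TAB>gene...`.
#' Duplicate genes within a term are deduplicated; a `level=N` token anywhere
#' in the description is parsed as the term's ontology level (depth), used by
#' the enrichment level filter.
#'
#' @param path Path to a GMT file.
#' @return Tibble with `term_id`, `term_name`, `level` (integer or `NA`) and
#'   a `genes` list-column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty GMT file")
  recs <- purrr::imap(lines, function(line, i) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(f) < 3 || length(genes) == 0) {
      abort(sprintf("malformed GMT line %d: need term id, description and >=1 gene", i))
    }
    lvl <- regmatches(f[2], regexpr("level=\\d+", f[2]))
    tibble(
      term_id = f[1],
      term_name = sub("\\s*level=\\d+\\s*", "", f[2]),
      level = if (length(lvl)) as.integer(sub("level=", "", lvl)) else NA_integer_,
      genes = list(genes)
    )
  })
  out <- bind_rows(recs)
  if (anyDuplicated(out$term_id)) abort("duplicate term ids in GMT file")
  out
}

#' Write annotations to a GMT file
#'
#' Inverse of [read_gmt()]; a non-missing `level` is appended to the
#' description as a `level=N` token.
#'
#' @param annotations Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(annotations, path) {
  lines <- purrr::pmap_chr(
    annotations[c("term_id", "term_name", "level", "genes")],
    function(term_id, term_name, level, genes) {
      desc <- if (is.na(level)) term_name else paste0(term_name, " level=", level)
      paste(c(term_id, desc, genes), collapse = "\t")
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Right-sided hypergeometric gene-set enrichment
#'
#' For each term, tests over-representation of the query in the term by the
#' upper hypergeometric tail `P(X >= overlap)` given the universe, then
#' BH-adjusts across all tested terms. Results are filtered to
#' `p < p_cut` and `FDR < fdr_cut`, and -- when level metadata is present --
#' to terms at ontology level `>= min_level` (deeper, more specific terms).
#' Terms are restricted to the universe before testing.
#'
#' @param query Character vector of genes of interest (must be a subset of
#'   `universe`).
#' @param annotations Annotation tibble as from [read_gmt()].
#' @param universe Character vector: the gene population the query was drawn
#'   from. There is no implicit default; the choice (all measured genes, the
#'   DE genes, ...) materially changes p-values and must be explicit.
#' @param p_cut,fdr_cut Raw-p and BH-FDR report cutoffs (defaults 0.05, 0.1).
#' @param min_level Minimum ontology level when levels are annotated
#'   (default 6); if no term has level metadata the filter is skipped with a
#'   warning.
#' @return Tibble with `term_id`, `term_name`, `level`, `overlap_count`,
#'   `term_size`, `query_size`, `universe_size`, `p_value`, `bh_fdr` and an
#'   `overlap_genes` list-column, sorted by ascending p. The unfiltered
#'   table is available as attribute `all_terms`.
#' @export
hypergeom_enrich <- function(query, annotations, universe, p_cut = 0.05,
                             fdr_cut = 0.1, min_level = 6) {
  query <- unique(query)
  universe <- unique(universe)
  offenders <- setdiff(query, universe)
  if (length(offenders) > 0) {
    abort(paste0("query genes not in universe: ", paste(offenders, collapse = ", ")))
  }
  tested <- annotations %>%
    mutate(
      genes = purrr::map(.data$genes, intersect, universe),
      term_size = lengths(.data$genes)
    ) %>%
    filter(.data$term_size > 0) %>%
    mutate(
      overlap_genes = purrr::map(.data$genes, intersect, query),
      overlap_count = lengths(.data$overlap_genes),
      query_size = length(query),
      universe_size = length(universe),
      p_value = phyper(.data$overlap_count - 1, .data$term_size,
        .data$universe_size - .data$term_size, .data$query_size,
        lower.tail = FALSE
      ),
      bh_fdr = bh_adjust(.data$p_value)
    ) %>%
    select(
      "term_id", "term_name", "level", "overlap_count", "term_size",
      "query_size", "universe_size", "p_value", "bh_fdr", "overlap_genes",
      "genes"
    ) %>%
    arrange(.data$p_value, .data$term_id)
  out <- filter(tested, .data$p_value < p_cut, .data$bh_fdr < fdr_cut)
  if (all(is.na(tested$level))) {
    if (nrow(out) > 0) warn("no ontology-level metadata in annotations; level filter skipped")
  } else {
    out <- filter(out, is.na(.data$level) | .data$level >= min_level)
  }
  attr(out, "all_terms") <- tested
  out
}

#' Keep triplets whose pair shares an enriched term
#'
#' Implements the biological-coherence rule for a switch triplet: X1 and X2
#' are expected to act in the same biological process. A triplet is retained
#' iff both pair members belong to at least one common enriched term; the
#' shared term ids are attached.
#'
#' @param triplets Triplet tibble with `x1_id`, `x2_id`.
#' @param enriched Enrichment tibble from [hypergeom_enrich()] (must carry
#'   the `genes` list-column).
#' @return The retained triplets with list-column `shared_terms` and a
#'   collapsed `shared_terms_str`.
#' @export
shared_term_triplets <- function(triplets, enriched) {
  if (nrow(enriched) == 0) {
    out <- triplets[0, ]
    out$shared_terms <- list()
    out$shared_terms_str <- character(0)
    return(out)
  }
  shared <- purrr::map2(triplets$x1_id, triplets$x2_id, function(a, b) {
    hit <- purrr::map_lgl(enriched$genes, function(g) a %in% g && b %in% g)
    enriched$term_id[hit]
  })
  out <- triplets
  out$shared_terms <- shared
  out$shared_terms_str <- purrr::map_chr(shared, paste, collapse = ";")
  filter(out, lengths(.data$shared_terms) > 0)
}
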