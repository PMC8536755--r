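#' Plug-in mutual information on equal-frequency bins
#'
#' Discretizes each vector into `n_bins` equal-frequency bins (near-equal
#' contiguous rank bins, ties stable by index) and returns the plug-in MI of
#' the 2-D histogram, in nats. A constant vector yields `MI = 0` by
#' convention. For `y = x` with `n` divisible by the bin count the joint
#' histogram is diagonal and `MI = log(n_bins)` exactly.
#'
#' @param x,y Numeric vectors of equal length `>= 3 * n_bins`.
#' @param n_bins Bins per axis; default `ceiling(n^(1/3))`, at least 3.
#' @return Mutual information in nats (non-negative).
#' @export
mutual_information <- function(x, y, n_bins = NULL) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length")
  k <- n_bins %||% max(3L, ceiling(n^(1 / 3)))
  if (n < 3 * k) abort(sprintf("need at least %d samples for %d bins", 3 * k, k))
  if (sd(x) == 0 || sd(y) == 0) return(0)
  lx <- bin_assign(x, k)
  ly <- bin_assign(y, k)
  joint <- tabulate(lx + k * (ly - 1L), nbins = k * k) / n
  px <- tabulate(lx, nbins = k) / n
  py <- tabulate(ly, nbins = k) / n
  pp <- outer(px, py)
  pos <- joint > 0
  sum(joint[pos] * log(joint[pos] / pp[pos]))
}

# MI matrix over all gene pairs from a genes x samples label matrix, via one
# crossprod per (bin_a, bin_b) cell; margins are the per-gene bin counts.
mi_matrix <- function(labels, k, n) {
  G <- nrow(labels)
  ind <- lapply(seq_len(k), function(a) t(labels == a) * 1) # samples x genes
  counts <- vapply(ind, colSums, numeric(G)) # G x k margins
  lmarg <- log(counts)
  mi <- matrix(0, G, G)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      N <- crossprod(ind[[a]], ind[[b]])
      term <- N / n * (log(N) + log(n) - outer(lmarg[, a], rep(1, G)) -
        outer(rep(1, G), lmarg[, b]))
      term[N == 0] <- 0
      mi <- mi + term
    }
  }
  mi
}

#' Build a mutual-information gene network with DPI pruning
#'
#' ARACNE-style reconstruction: all pairwise MIs are estimated on
#' equal-frequency histograms, each edge gets a permutation p-value (gene
#' label vectors independently permuted per round, nulls shared across
#' pairs), edges with `p >= p_cut` are removed, and the data-processing
#' inequality is applied to every remaining triangle: the weakest edge is
#' removed when its MI is below `(1 - dpi_tolerance)` times the smaller of
#' the other two, the rationale being that for a Markov chain X - Y - Z the
#' indirect X-Z dependence can never exceed either direct one. Genes with
#' constant expression contribute MI 0 and end up isolated.
#'
#' @param x Expression tibble or matrix (genes x samples).
#' @param p_cut Permutation p-value threshold for keeping an edge
#'   (default 0.05).
#' @param n_perm Permutation rounds (default 99).
#' @param dpi_tolerance DPI tolerance in `[0, 1]`; 0 is the strictest
#'   pruning (default 0.1).
#' @param n_bins Histogram bins per axis (default `ceiling(n^(1/3))`,
#'   min 3).
#' @param seed Integer seed for the permutation null.
#' @return Object of class `gene_network`: fields `nodes`, `edges` (tibble
#'   `gene_a`, `gene_b`, `mi`, `p_value`), `n_edges_pre_dpi`, `params`.
#' @export
build_mi_network <- function(x, p_cut = 0.05, n_perm = 99, dpi_tolerance = 0.1,
                             n_bins = NULL, seed = 1L) {
  m <- as_expr_matrix(x)
  check_finite(m)
  G <- nrow(m)
  n <- ncol(m)
  if (G < 3) abort("need at least 3 genes")
  k <- n_bins %||% max(3L, ceiling(n^(1 / 3)))
  if (n < 3 * k) abort(sprintf("need at least %d samples for %d bins", 3 * k, k))
  ids <- rownames(m)
  constant <- apply(m, 1, function(v) sd(v) == 0)
  labels <- t(apply(m, 1, bin_assign, m = k))

  mi <- mi_matrix(labels, k, n)
  mi[constant, ] <- 0
  mi[, constant] <- 0

  cnt <- matrix(0, G, G)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      lp <- t(apply(labels, 1, sample))
      null_mi <- mi_matrix(lp, k, n)
      cnt <- cnt + (null_mi >= mi)
    }
  })
  pval <- (1 + cnt) / (n_perm + 1)

  adj <- pval < p_cut
  adj[constant, ] <- FALSE
  adj[, constant] <- FALSE
  diag(adj) <- FALSE
  adj <- adj | t(adj) # symmetrize (mi and the shared null are symmetric anyway)
  n_pre <- sum(adj[upper.tri(adj)])

  # DPI, marked against the pre-pruning MI matrix and removed afterwards.
  drop <- matrix(FALSE, G, G)
  edge_idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  tol <- 1 - dpi_tolerance
  for (e in seq_len(nrow(edge_idx))) {
    i <- edge_idx[e, 1]
    j <- edge_idx[e, 2]
    common <- which(adj[i, ] & adj[j, ])
    if (length(common) && any(mi[i, j] < tol * pmin(mi[i, common], mi[j, common]))) {
      drop[i, j] <- TRUE
    }
  }
  adj[drop | t(drop)] <- FALSE

  keep <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- tibble(
    gene_a = ids[keep[, 1]], gene_b = ids[keep[, 2]],
    mi = mi[keep], p_value = pval[keep]
  ) %>% arrange(desc(.data$mi))
  structure(
    list(
      nodes = ids, edges = edges, n_edges_pre_dpi = n_pre,
      params = list(
        p_cut = p_cut, n_perm = n_perm, dpi_tolerance = dpi_tolerance,
        n_bins = k, seed = seed
      )
    ),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "Mutual-information gene network: %d nodes, %d edges (%d before DPI pruning)\n",
    length(x$nodes), nrow(x$edges), x$n_edges_pre_dpi
  ))
  invisible(x)
}

#' Tidiers for gene networks
#'
#' `tidy()` returns the edge table; `glance()` a one-row summary.
#'
#' @param x A `gene_network`.
#' @param ... Unused.
#' @method tidy gene_network
#' @export
tidy.gene_network <- function(x, ...) x$edges

#' @rdname tidy.gene_network
#' @method glance gene_network
#' @export
glance.gene_network <- function(x, ...) {
  tibble(
    n_nodes = length(x$nodes), n_edges = nrow(x$edges),
    n_edges_pre_dpi = x$n_edges_pre_dpi,
    p_cut = x$params$p_cut, dpi_tolerance = x$params$dpi_tolerance,
    n_bins = x$params$n_bins
  )
}

network_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[c("gene_a", "gene_b", "mi", "p_value")],
    directed = FALSE,
    vertices = network$nodes
  )
}

#' Test regulatory path support for triplets
#'
#' A triplet is network-supported when the switch gene X3 reaches both X1 and
#' X2 through short paths: each shortest path may contain at most
#' `max_intermediates` interior genes (i.e. at most `max_intermediates + 1`
#' edges). Genes absent from the network are unsupported.
#'
#' @param network A [build_mi_network()] result.
#' @param triplets Triplet tibble with `x1_id`, `x2_id`, `x3_id`.
#' @param max_intermediates Maximum interior genes per path (default 2).
#' @return `triplets` with added columns `supported` (logical), `path_x1`,
#'   `path_x2` (witnessing shortest paths as `a->b->c` strings, `NA` when
#'   absent).
#' @export
triplet_path_support <- function(network, triplets, max_intermediates = 2) {
  g <- network_igraph(network)
  max_edges <- max_intermediates + 1
  path_to <- function(from, to) {
    if (!(from %in% network$nodes) || !(to %in% network$nodes)) {
      return(NA_character_)
    }
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = from, to = to, output = "vpath")
    )$vpath[[1]]
    if (length(sp) < 2 || length(sp) - 1 > max_edges) {
      return(NA_character_)
    }
    paste(names(sp), collapse = "->")
  }
  out <- triplets
  out$path_x1 <- purrr::map2_chr(triplets$x3_id, triplets$x1_id, path_to)
  out$path_x2 <- purrr::map2_chr(triplets$x3_id, triplets$x2_id, path_to)
  out$supported <- !is.na(out$path_x1) & !is.na(out$path_x2)
  out
}

#' Extract the subnetwork around supported triplets
#'
#' Induced edge set over all genes on the witnessing paths of the given
#' (supported) triplets, for figure-style reporting.
#'
#' @param network A `gene_network`.
#' @param supported_triplets Output rows of [triplet_path_support()] with
#'   `supported == TRUE`.
#' @return Edge tibble (subset of `network$edges`) with attribute `nodes`.
#' @export
triplet_subnetwork <- function(network, supported_triplets) {
  nodes <- unique(unlist(strsplit(
    stats::na.omit(c(supported_triplets$path_x1, supported_triplets$path_x2)),
    "->",
    fixed = TRUE
  )))
  edges <- filter(
    network$edges,
    .data$gene_a %in% nodes & .data$gene_b %in% nodes
  )
  attr(edges, "nodes") <- nodes
  edges
}

#' Write a network edge list
#'
#' @param network A `gene_network`.
#' @param path Output path.
#' @param format `"tsv"` (edge list) or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(network$edges, path)
  } else {
    igraph::write_graph(network_igraph(network), path, format = "graphml")
  }
  invisible(path)
}
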