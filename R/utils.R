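#' Coerce an expression table to a numeric matrix
#'
#' User-facing functions accept expression data either as a tibble whose first
#' column holds gene identifiers (remaining columns one per sample) or as a
#' numeric matrix with gene rownames. This helper normalises both to a matrix.
#'
#' @param x Expression tibble/data frame (gene ids in column 1) or numeric
#'   matrix with rownames.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @keywords internal
as_expr_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("expression matrix must have gene rownames")
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x)) abort("expression data must be a data frame or matrix")
  if (ncol(x) < 2) abort("expression table needs a gene-id column plus >=1 sample column")
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Convert an expression matrix to a tibble
#'
#' @param m Numeric matrix with gene rownames.
#' @param id_col Name of the identifier column.
#' @return Tibble with the identifier column first.
#' @export
expr_tibble <- function(m, id_col = "gene_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(!!id_col := rownames(m)), out)
  out
}

check_finite <- function(m, what = "expression matrix") {
  if (anyNA(m) || any(!is.finite(m))) {
    abort(paste0(what, " contains missing or non-finite values; impute or filter first"))
  }
  invisible(m)
}

#' Near-equal contiguous bin sizes
#'
#' Splits `n` items into `m` contiguous bins whose sizes differ by at most one,
#' with the larger bins first (i.e. at the low end of the sorted variable).
#'
#' @keywords internal
bin_sizes <- function(n, m) {
  base <- n %/% m
  rem <- n %% m
  base + as.integer(seq_len(m) <= rem)
}

#' Bin membership along a sorting variable
#'
#' Returns, for each observation, its bin index when observations are ordered
#' by `x` (ties broken by original index, i.e. a stable sort) and cut into `m`
#' contiguous near-equal bins.
#'
#' @keywords internal
bin_assign <- function(x, m) {
  n <- length(x)
  sizes <- bin_sizes(n, m)
  ord <- order(x, seq_along(x))
  idx <- rep.int(seq_len(m), sizes)
  out <- integer(n)
  out[ord] <- idx
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
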