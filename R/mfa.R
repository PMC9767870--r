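#' Multiple-factor analysis across expression tables
#'
#' Extension of PCA to several tables sharing observations. Here the
#' observations are genes (restricted to those shared by all tables) and
#' each table contributes its cells as variables. Every cell profile is
#' centered and unit-scaled across genes, each table is divided by its
#' first singular value so no single table dominates, the weighted tables
#' are concatenated and a global SVD taken. Per-dimension table
#' contributions are the summed squared loadings of each table's cells, in
#' percent (they sum to 100 per dimension).
#'
#' @param tables List of >= 2 genes x cells normalized matrices.
#' @param n_dims Dimensions to retain (default 5).
#' @return List of class `mfa_result`: `gene_scores` (genes x dims,
#'   singular-value scaled), `cell_loadings` (cells x dims), `table` (table
#'   index per cell), `contributions` (tables x dims, percent), `eig`.
#' @export
run_mfa <- function(tables, n_dims = 5) {
  if (length(tables) < 2) stop_fmt("run_mfa needs at least 2 tables")
  if (is.null(names(tables)))
    names(tables) <- paste0("table", seq_along(tables))
  shared <- Reduce(intersect, lapply(tables, rownames))
  if (!length(shared)) stop_fmt("tables share no genes")
  scaled <- lapply(names(tables), function(nm) {
    x <- as.matrix(tables[[nm]][shared, , drop = FALSE])
    sds <- apply(x, 2, sd)
    if (any(sds == 0))
      stop_fmt("table '%s' has zero-variance cells", nm)
    x <- scale(x)
    x / svd(x, nu = 0, nv = 0)$d[1]
  })
  names(scaled) <- names(tables)
  concat <- do.call(cbind, scaled)
  table_of <- rep(names(tables),
                  vapply(scaled, ncol, integer(1)))
  sv <- svd(concat)
  n_dims <- min(n_dims, length(sv$d))
  gene_scores <- sv$u[, seq_len(n_dims), drop = FALSE] %*%
    diag(sv$d[seq_len(n_dims)], n_dims)
  rownames(gene_scores) <- shared
  cell_loadings <- sv$v[, seq_len(n_dims), drop = FALSE]
  rownames(cell_loadings) <- colnames(concat)
  contributions <- t(sapply(names(tables), function(nm) {
    idx <- table_of == nm
    100 * colSums(cell_loadings[idx, , drop = FALSE]^2)
  }))
  colnames(contributions) <- paste0("dim", seq_len(n_dims))
  colnames(gene_scores) <- colnames(cell_loadings) <-
    paste0("dim", seq_len(n_dims))
  structure(list(gene_scores = gene_scores, cell_loadings = cell_loadings,
                 table = table_of, contributions = contributions,
                 eig = sv$d^2), class = "mfa_result")
}
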