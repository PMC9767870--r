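#' Cluster cells by modularity community detection
#'
#' PCA on scaled highly variable genes, a k-nearest-neighbor graph on the
#' retained components, and Louvain modularity communities at the given
#' resolution. Deterministic under a fixed seed.
#'
#' @param norm Genes x cells normalized matrix.
#' @param n_pcs Principal components retained (default 15).
#' @param resolution Louvain resolution parameter (default 0.52).
#' @param k Neighbors per cell (default 20; reduced with a message when
#'   there are fewer cells).
#' @param hvg Optional gene set to use; defaults to [select_hvg()] output
#'   (capped at 500 genes), falling back to all genes when selection is
#'   too small.
#' @param seed Seed.
#' @return Named integer vector of cluster labels (1-based).
#' @export
cluster_cells <- function(norm, n_pcs = 15, resolution = 0.52, k = 20,
                          hvg = NULL, seed = 1L) {
  n <- ncol(norm)
  if (n < 2 * n_pcs) stop_fmt("need at least %d cells for %d PCs",
                              2 * n_pcs, n_pcs)
  if (is.null(hvg)) {
    hvg <- head(suppressWarnings(select_hvg(norm)), 500)
    if (length(hvg) < 20) hvg <- rownames(norm)
  }
  x <- as.matrix(norm[hvg, , drop = FALSE])
  sds <- apply(x, 1, sd)
  x <- x[sds > 0, , drop = FALSE]
  x <- (x - rowMeans(x)) / apply(x, 1, sd)
  n_pcs <- min(n_pcs, nrow(x) - 1, n - 1)
  pcs <- with_seed(seed, prcomp(t(x), rank. = n_pcs)$x)
  if (k >= n) {
    message(sprintf("cluster_cells: k reduced from %d to %d", k, n - 1))
    k <- n - 1
  }
  d <- as.matrix(dist(pcs))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[2:(k + 1)]
    cbind(i, nb)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- with_seed(seed,
                    igraph::cluster_louvain(g, resolution = resolution))
  out <- as.integer(igraph::membership(comm))
  names(out) <- colnames(norm)
  out
}

#' Assign T-cell clusters to phenotypes by marker scores
#'
#' Each cluster receives the marker set with the highest mean module score
#' among its cells; cells inherit their cluster's label. Clusters whose
#' scores are all negative are labelled `"unassigned"`.
#'
#' @param clusters Named cluster labels from [cluster_cells()].
#' @param norm Genes x cells normalized matrix restricted to T/NK cells.
#' @param markers Named list of marker gene sets (default
#'   [default_t_markers()]: exhausted, regulatory, proliferating, NK).
#' @param seed Seed for control-gene sampling.
#' @return Named character vector of per-cell labels.
#' @export
classify_t_subsets <- function(clusters, norm, markers = default_t_markers(),
                               seed = 1L) {
  scores <- sapply(seq_along(markers), function(i)
    module_score(norm, markers[[i]], seed = seed + i))
  colnames(scores) <- names(markers)
  out <- character(length(clusters))
  names(out) <- names(clusters)
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    m <- colMeans(scores[idx, , drop = FALSE])
    if (all(m < 0)) {
      message(sprintf("classify_t_subsets: cluster %s unassigned", cl))
      out[idx] <- "unassigned"
    } else {
      out[idx] <- names(markers)[which.max(m)]
    }
  }
  out
}

#' @importFrom stats dist
NULL
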