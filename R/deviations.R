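#' Background-matched peak sets
#'
#' Maps every peak to a (GC content, mean accessibility) bin on a quantile
#' grid and builds `n_sets` background sets in which each peak is replaced
#' by a random peak from its bin. Bins with fewer than `min_bin` peaks are
#' merged into the global pool.
#'
#' @param peaks Peaks x cells count matrix.
#' @param gc Per-peak GC fractions (same order as rows).
#' @param n_sets Number of background sets (default 50).
#' @param n_bins_gc,n_bins_acc Bins for GC and mean accessibility
#'   (default 10 each).
#' @param min_bin Minimum bin occupancy before merging (default 3).
#' @param seed Seed.
#' @return Integer matrix peaks x n_sets of replacement peak indices.
#' @export
background_peak_sets <- function(peaks, gc, n_sets = 50, n_bins_gc = 10,
                                 n_bins_acc = 10, min_bin = 3, seed = 1L) {
  n <- nrow(peaks)
  stopifnot(length(gc) == n)
  acc <- row_means(peaks)
  bin <- paste(rank_bins(gc, n_bins_gc), rank_bins(acc, n_bins_acc))
  occ <- table(bin)
  sparse <- names(occ)[occ < min_bin]
  bin[bin %in% sparse] <- "merged"
  with_seed(seed, {
    out <- matrix(0L, n, n_sets)
    for (b in unique(bin)) {
      idx <- which(bin == b)
      pool <- if (b == "merged") seq_len(n) else idx
      out[idx, ] <- sample(pool, length(idx) * n_sets, replace = TRUE)
    }
    rownames(out) <- rownames(peaks)
    out
  })
}

#' Motif accessibility deviations against matched backgrounds
#'
#' For motif m and cell c the raw deviation is `d = (X - E) / E`, where X
#' is the cell's count total over the motif's member peaks and E is the
#' expected total given the cell's depth and the member peaks' share of all
#' counts. The z-score standardizes d against the same statistic computed
#' over GC/accessibility-matched background peak sets.
#'
#' @param peaks Peaks x cells count matrix.
#' @param membership Named list: motif -> character vector of member peak
#'   ids (or integer indices).
#' @param bg_sets Background index matrix from [background_peak_sets()].
#' @return Motifs x cells matrix of deviation z-scores; raw deviations in
#'   attribute `"raw"`.
#' @export
compute_deviations <- function(peaks, membership, bg_sets) {
  if (!length(membership)) stop_fmt("membership must be non-empty")
  peak_tot <- if (is(peaks, "Matrix")) Matrix::rowSums(peaks) else
    rowSums(peaks)
  cell_tot <- col_sums(peaks)
  grand <- sum(peak_tot)
  n_sets <- ncol(bg_sets)
  dev_of <- function(idx) {
    X <- col_sums(peaks[idx, , drop = FALSE])
    E <- (sum(peak_tot[idx]) / grand) * cell_tot
    d <- ifelse(E > 0, (X - E) / E, 0)
    d
  }
  z <- matrix(0, length(membership), ncol(peaks),
              dimnames = list(names(membership), colnames(peaks)))
  raw <- z
  for (mi in seq_along(membership)) {
    idx <- membership[[mi]]
    if (is.character(idx)) idx <- match(idx, rownames(peaks))
    if (any(is.na(idx)) || !length(idx))
      stop_fmt("motif '%s' has invalid member peaks", names(membership)[mi])
    if (length(unique(idx)) == nrow(peaks)) {
      # member set is the whole universe: X = E identically, so both the
      # raw deviation and its standardization are exactly zero
      next
    }
    d <- dev_of(idx)
    bg <- vapply(seq_len(n_sets), function(s) dev_of(bg_sets[idx, s]),
                 numeric(ncol(peaks)))
    mu <- rowMeans(bg)
    s <- apply(bg, 1, sd)
    # below ~1e-8 the background spread is numerical noise, not signal
    zz <- ifelse(s > 1e-8, (d - mu) / s, 0)
    if (any(s == 0) && any(d - mu != 0))
      message(sprintf("compute_deviations: zero background sd for '%s'; z set to 0",
                      names(membership)[mi]))
    raw[mi, ] <- d
    z[mi, ] <- zz
  }
  attr(z, "raw") <- raw
  z
}

#' Differential motif deviations between two cell groups
#'
#' Per-motif Welch t-test of deviation z-scores between the groups, with
#' Storey q-values (BH fallback for small motif sets).
#'
#' @param dev Motifs x cells deviation matrix.
#' @param group1,group2 Cell id vectors (each >= 3 cells).
#' @param fdr_method `"storey"` (default) or `"BH"`.
#' @return data.frame with `motif`, `t`, `p`, `q`, `significant`
#'   (q < 0.05).
#' @export
differential_deviations <- function(dev, group1, group2,
                                    fdr_method = c("storey", "BH")) {
  fdr_method <- match.arg(fdr_method)
  if (length(group1) < 3 || length(group2) < 3)
    stop_fmt("each group needs >= 3 cells")
  res <- row_welch(dev[, group1, drop = FALSE], dev[, group2, drop = FALSE])
  q <- if (fdr_method == "storey") storey_qvalue(res$p) else
    p.adjust(res$p, "BH")
  data.frame(motif = rownames(dev), t = res$t, p = res$p, q = as.numeric(q),
             significant = as.numeric(q) < 0.05, stringsAsFactors = FALSE,
             row.names = NULL)
}

# Vectorized Welch t-test across rows; zero-variance rows get p = 1.
row_welch <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- row_vars(x); v2 <- row_vars(y)
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) +
                          v2^2 / (n2^2 * (n2 - 1))),
               1)
  p <- ifelse(se2 > 0, 2 * pt(abs(t), df, lower.tail = FALSE), 1)
  list(t = t, p = p, df = df)
}

#' Cluster cells by motif-deviation profiles
#'
#' Average-linkage hierarchical clustering of the inter-cell Pearson
#' correlation matrix of motif deviations, with the polarization statistics
#' at a 2-way cut: median within-cluster and between-cluster correlations.
#'
#' @param dev Motifs x cells deviation matrix (>= 2 cells; constant cells
#'   are dropped with a message).
#' @param k Number of clusters at the cut (default 2).
#' @return List with `hclust`, `clusters`, `cor` (cell correlation
#'   matrix), `median_within` (per cluster), `median_between`.
#' @export
cluster_motif_profiles <- function(dev, k = 2) {
  if (ncol(dev) < 2) stop_fmt("need >= 2 cells")
  sds <- apply(dev, 2, sd)
  if (any(sds == 0)) {
    message(sprintf("cluster_motif_profiles: dropping %d constant cells",
                    sum(sds == 0)))
    dev <- dev[, sds > 0, drop = FALSE]
  }
  cc <- cor(dev)
  hc <- hclust(as.dist(1 - cc), method = "average")
  cl <- cutree(hc, k = k)
  within <- vapply(seq_len(k), function(i) {
    idx <- which(cl == i)
    if (length(idx) < 2) return(NA_real_)
    median(cc[idx, idx][upper.tri(cc[idx, idx])])
  }, numeric(1))
  between <- if (k == 2) {
    median(cc[cl == 1, cl == 2, drop = FALSE])
  } else NA_real_
  list(hclust = hc, clusters = cl, cor = cc,
       median_within = within, median_between = between)
}

#' @importFrom stats median
NULL
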