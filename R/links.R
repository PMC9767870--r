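#' Link enhancers to genes by meta-cell correlation
#'
#' Cells are aggregated into meta-cells by k-means in a joint embedding of
#' the normalized expression and accessibility profiles (stabilizing the
#' sparse per-cell signal), and every peak-gene pair whose peak lies within
#' `window_bp` of the gene body is tested by Pearson correlation of the
#' meta-cell mean profiles. Positive correlations with BH q below `q_max`
#' (adjusted across all tested pairs) are returned as links.
#'
#' @param peaks Peaks x cells count matrix.
#' @param norm Genes x cells normalized expression matrix (cells shared
#'   with `peaks`).
#' @param peak_intervals data.frame `peak_id`, `chromosome`, `start`,
#'   `end` (0-based half-open).
#' @param annot Gene annotation (`gene_id`, `chromosome`, `start`, `end`).
#' @param window_bp Cis window around the gene body (default 250 kb).
#' @param n_metacells Number of meta-cells (default 100; reduced when
#'   there are fewer cells).
#' @param q_max q-value threshold (default 0.05).
#' @param n_pcs Embedding dimensions for meta-cell construction.
#' @param seed Seed.
#' @return data.frame of links: `peak_id`, `gene_id`, `distance`, `r`,
#'   `p`, `q`; all tested pairs are in attribute `"tested"`.
#' @export
link_enhancers <- function(peaks, norm, peak_intervals, annot,
                           window_bp = 250000, n_metacells = 100,
                           q_max = 0.05, n_pcs = 20, seed = 1L) {
  cells <- intersect(colnames(peaks), colnames(norm))
  if (length(cells) < 2 * n_metacells)
    n_metacells <- max(2, length(cells) %/% 2)
  pk <- peaks[, cells, drop = FALSE]
  rna <- norm[, cells, drop = FALSE]
  pk_norm <- log_normalize_safe(pk)

  # candidate pairs within the cis window
  pairs <- cis_pairs(peak_intervals, annot, window_bp)
  if (!nrow(pairs)) {
    message("link_enhancers: no peak-gene pairs within window")
    out <- data.frame(peak_id = character(), gene_id = character(),
                      distance = numeric(), r = numeric(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE)
    attr(out, "tested") <- out
    return(out)
  }

  # joint embedding -> meta-cells
  feats <- rbind(top_variable_rows(rna, 500), top_variable_rows(pk_norm, 500))
  feats <- feats[apply(feats, 1, sd) > 0, , drop = FALSE]
  feats <- (feats - rowMeans(feats)) / apply(feats, 1, sd)
  n_pcs <- min(n_pcs, nrow(feats) - 1, length(cells) - 1)
  emb <- with_seed(seed, {
    pcs <- prcomp(t(feats), rank. = n_pcs)$x
    n_distinct <- nrow(unique(round(pcs, 8)))
    k <- min(n_metacells, max(2, n_distinct))
    km <- kmeans(pcs, centers = k, iter.max = 50, nstart = 3)
    km$cluster
  })
  gene_prof <- t(rowsum(t(as.matrix(rna[unique(pairs$gene_id), ,
                                        drop = FALSE])), emb) /
                   as.vector(table(emb)))
  peak_prof <- t(rowsum(t(as.matrix(pk_norm[unique(pairs$peak_id), ,
                                            drop = FALSE])), emb) /
                   as.vector(table(emb)))

  k <- ncol(gene_prof)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    g <- gene_prof[pairs$gene_id[i], ]
    p <- peak_prof[pairs$peak_id[i], ]
    if (sd(g) == 0 || sd(p) == 0) return(NA_real_)
    cor(g, p)
  }, numeric(1))
  if (k < 3) {
    message("link_enhancers: fewer than 3 meta-cells; correlations are ",
            "reported without p-values")
    p <- rep(NA_real_, length(r))
  } else {
    tstat <- r * sqrt((k - 2) / pmax(1 - r^2, 1e-12))
    p <- 2 * pt(abs(tstat), df = k - 2, lower.tail = FALSE)
  }
  pairs$r <- r
  pairs$p <- p
  pairs$q <- p.adjust(p, method = "BH")
  links <- pairs[!is.na(pairs$r) & pairs$q < q_max & pairs$r > 0, ,
                 drop = FALSE]
  rownames(links) <- NULL
  attr(links, "tested") <- pairs
  links
}

cis_pairs <- function(peak_intervals, annot, window_bp) {
  out <- list()
  for (chr in intersect(unique(peak_intervals$chromosome),
                        unique(annot$chromosome))) {
    pk <- peak_intervals[peak_intervals$chromosome == chr, , drop = FALSE]
    gn <- annot[annot$chromosome == chr, , drop = FALSE]
    for (i in seq_len(nrow(gn))) {
      gap <- pmax(0, pmax(gn$start[i] - pk$end, pk$start - gn$end[i]))
      hit <- which(gap <= window_bp)
      if (length(hit))
        out[[length(out) + 1]] <- data.frame(
          peak_id = pk$peak_id[hit], gene_id = gn$gene_id[i],
          distance = gap[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

log_normalize_safe <- function(counts) {
  tot <- col_sums(counts)
  if (any(tot == 0)) {
    # zero-depth cells carry no information; keep them as all-zero columns
    out <- log_normalize(counts[, tot > 0, drop = FALSE])
    full <- matrix(0, nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
    full[, tot > 0] <- as.matrix(out)
    return(full)
  }
  log_normalize(counts)
}

top_variable_rows <- function(x, n) {
  v <- row_vars(x)
  x[order(v, decreasing = TRUE)[seq_len(min(n, nrow(x)))], , drop = FALSE]
}

#' Intersect evidence into a cis-regulome
#'
#' A gene enters the regulome iff it is in the upregulated set and has at
#' least one linked peak that both carries the motif and is in the
#' state-specific peak set. The supporting peak evidence is recorded per
#' gene. Monotone: enlarging any evidence set never removes a gene.
#'
#' @param de_up Character vector of upregulated genes (e.g. MES-up from
#'   [hurdle_de()]).
#' @param links Link table from [link_enhancers()].
#' @param motif_peaks Character vector of motif-bearing peak ids.
#' @param specific_peaks Character vector of state-specific peak ids.
#' @return List of class `regulome`: `genes` and `support` (data.frame
#'   gene_id, peak_id, r, distance).
#' @export
infer_regulome <- function(de_up, links, motif_peaks, specific_peaks) {
  sup <- links[links$gene_id %in% de_up &
                 links$peak_id %in% motif_peaks &
                 links$peak_id %in% specific_peaks, , drop = FALSE]
  structure(list(genes = sort(unique(sup$gene_id)),
                 support = sup[, c("gene_id", "peak_id", "r", "distance")]),
            class = "regulome")
}

#' @export
print.regulome <- function(x, ...) {
  cat(sprintf("regulome: %d genes, %d supporting links\n",
              length(x$genes), nrow(x$support)))
  invisible(x)
}
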