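#' Module score against bin-matched control genes
#'
#' Background-adjusted program activity: genes are placed into `n_bins`
#' equal-occupancy bins of cohort mean expression; each signature gene
#' contributes `n_ctrl` control genes drawn from its bin; the score of a
#' cell is the mean normalized expression of the signature genes minus the
#' mean over the sampled control genes. A signature distributed like its
#' controls therefore scores ~0.
#'
#' @param norm Genes x cells normalized matrix.
#' @param sig Character vector of signature gene ids (genes absent from the
#'   matrix are dropped with a warning).
#' @param n_bins Number of expression bins (default 25).
#' @param n_ctrl Control genes sampled per signature gene (default 100);
#'   bins smaller than `n_ctrl` are sampled with replacement (logged).
#' @param seed Seed for control sampling.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(norm, sig, n_bins = 25, n_ctrl = 100, seed = 1L) {
  sig <- unique(as.character(sig))
  present <- intersect(sig, rownames(norm))
  if (!length(present))
    stop_fmt("no signature genes present in the matrix")
  if (length(present) < length(sig))
    warn_fmt("%d of %d signature genes absent; dropped",
             length(sig) - length(present), length(sig))
  mu <- row_means(norm)
  bins <- rank_bins(mu, n_bins)
  names(bins) <- rownames(norm)
  with_seed(seed, {
    ctrl_idx <- integer(0)
    replaced <- FALSE
    for (g in present) {
      pool <- which(bins == bins[[g]])
      if (length(pool) < n_ctrl) replaced <- TRUE
      ctrl_idx <- c(ctrl_idx,
                    sample(pool, n_ctrl, replace = length(pool) < n_ctrl))
    }
    if (replaced)
      message("module_score: some bins smaller than n_ctrl; ",
              "sampled with replacement")
    sig_mean <- col_means(norm[present, , drop = FALSE])
    ctrl_mean <- col_means(norm[ctrl_idx, , drop = FALSE])
    out <- as.numeric(sig_mean - ctrl_mean)
    names(out) <- colnames(norm)
    out
  })
}

#' Classify malignant cells as proneural or mesenchymal
#'
#' Symmetric signature-score argmax: a cell is MES when its MES module
#' score strictly exceeds its PN score; ties go to PN (tie count logged).
#'
#' @param pn_score,mes_score Per-cell module scores (same cells, computed
#'   on malignant cells).
#' @return Character vector of labels `"PN"`/`"MES"`.
#' @export
classify_pn_mes <- function(pn_score, mes_score) {
  stopifnot(length(pn_score) == length(mes_score))
  ties <- sum(mes_score == pn_score)
  if (ties > 0)
    message(sprintf("classify_pn_mes: %d ties assigned to PN", ties))
  out <- ifelse(mes_score > pn_score, "MES", "PN")
  names(out) <- names(pn_score)
  out
}

#' Classify cycling cells
#'
#' A cell is cycling when its cycling-program module score is strictly
#' positive.
#'
#' @param cyc_score Per-cell module score of the cycling program.
#' @return Named logical vector.
#' @export
classify_cycling <- function(cyc_score) {
  out <- cyc_score > 0
  names(out) <- names(cyc_score)
  out
}

#' Classify monocytic activation state
#'
#' M0 (unactivated) when both the M1 and M2 module scores are below zero;
#' otherwise the higher of the two scores decides, with exact ties broken
#' toward M1 (tie count logged).
#'
#' @param m1_score,m2_score Per-cell module scores on monocytic cells.
#' @return Character vector of labels `"M0"`/`"M1"`/`"M2"`.
#' @export
classify_m_state <- function(m1_score, m2_score) {
  stopifnot(length(m1_score) == length(m2_score))
  out <- ifelse(m1_score < 0 & m2_score < 0, "M0",
                ifelse(m1_score >= m2_score, "M1", "M2"))
  ties <- sum(!(m1_score < 0 & m2_score < 0) & m1_score == m2_score)
  if (ties > 0)
    message(sprintf("classify_m_state: %d argmax ties assigned to M1", ties))
  names(out) <- names(m1_score)
  out
}

#' Per-sample composition table
#'
#' @param cell_meta data.frame with `cell_id` and `sample_id`.
#' @param labels Named or cell-ordered vector of per-cell labels.
#' @return data.frame: one row per sample, one column per label, entries in
#'   percent (rows sum to 100).
#' @export
composition_table <- function(cell_meta, labels) {
  if (!is.null(names(labels))) labels <- labels[cell_meta$cell_id]
  if (length(labels) != nrow(cell_meta) || any(is.na(labels)))
    stop_fmt("every cell must be labelled")
  tab <- table(cell_meta$sample_id, labels)
  pct <- sweep(tab, 1, rowSums(tab), "/") * 100
  df <- as.data.frame.matrix(pct)
  df <- cbind(sample_id = rownames(df), df)
  rownames(df) <- NULL
  df
}
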