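#' Hurdle-model differential expression between two cell groups
#'
#' Two-part single-cell expression model per gene: a Bernoulli detection
#' component (expression > 0) and a Gaussian component on the positive
#' log-normalized values, each with a group effect in the full model and
#' pooled in the null. The likelihood-ratio statistic
#' `2 * (loglik_full - loglik_null)` is referred to chi-squared with 2 df
#' (one df per component); q-values are Benjamini-Hochberg. Gaussian
#' variances are profiled per model. Genes detected in no cell are skipped.
#'
#' @param norm Genes x cells normalized matrix.
#' @param group1,group2 Cell id (or index) vectors, each >= 10 cells.
#' @return data.frame with `gene`, `logFC` (group2 minus group1 mean of
#'   normalized expression), `det1`, `det2` (detection rates), `lrt`, `p`,
#'   `q`.
#' @export
hurdle_de <- function(norm, group1, group2) {
  if (length(group1) < 10 || length(group2) < 10)
    stop_fmt("each group needs >= 10 cells")
  x1 <- norm[, group1, drop = FALSE]
  x2 <- norm[, group2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)

  k1 <- as.numeric(col_to_row_sums(x1 > 0))
  k2 <- as.numeric(col_to_row_sums(x2 > 0))
  s1 <- as.numeric(col_to_row_sums(x1))
  s2 <- as.numeric(col_to_row_sums(x2))
  ss1 <- as.numeric(col_to_row_sums(x1^2))
  ss2 <- as.numeric(col_to_row_sums(x2^2))

  keep <- (k1 + k2) > 0
  # Bernoulli log-likelihood difference (group rates vs pooled rate)
  bern <- function(k, n) {
    p <- k / n
    ifelse(k > 0, k * log(p), 0) + ifelse(n - k > 0, (n - k) * log(1 - p), 0)
  }
  ll_b_full <- bern(k1, n1) + bern(k2, n2)
  ll_b_null <- bern(k1 + k2, n1 + n2)

  # Gaussian component on positives, variance profiled per model
  m <- k1 + k2
  rss_full <- pmax(ifelse(k1 > 0, ss1 - s1^2 / k1, 0) +
                     ifelse(k2 > 0, ss2 - s2^2 / k2, 0), 0)
  rss_null <- pmax(ss1 + ss2 - (s1 + s2)^2 / pmax(m, 1), 0)
  eps <- 1e-8
  gauss_term <- ifelse(m > 1,
                       m * log(pmax(rss_null, eps * m) /
                                 pmax(rss_full, eps * m)),
                       0)
  lrt <- 2 * (ll_b_full - ll_b_null) + gauss_term
  lrt <- pmax(lrt, 0)
  p <- pchisq(lrt, df = 2, lower.tail = FALSE)
  logFC <- s2 / n2 - s1 / n1

  out <- data.frame(gene = rownames(norm), logFC = logFC,
                    det1 = k1 / n1, det2 = k2 / n2, lrt = lrt, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[keep, , drop = FALSE]
  out$q <- p.adjust(out$p, method = "BH")
  out
}

col_to_row_sums <- function(x) {
  if (is(x, "Matrix")) Matrix::rowSums(x) else rowSums(x)
}

#' Differentially accessible peaks between two cell groups
#'
#' Welch t-test on log-normalized per-peak counts with BH correction; used
#' to define state-specific (e.g. MES-specific) peak sets.
#'
#' @param peaks Peaks x cells count matrix.
#' @param group1,group2 Cell id vectors; `group2` is the state of
#'   interest (positive t means higher in `group2`).
#' @param q_max q-value threshold for the returned specific set.
#' @return List with `table` (peak, t, p, q) and `specific` (peak ids
#'   with q < `q_max` and higher accessibility in `group2`).
#' @export
differential_accessibility <- function(peaks, group1, group2, q_max = 0.05) {
  tot <- col_sums(peaks)
  if (any(tot == 0)) {
    keep <- colnames(peaks)[tot > 0]
    group1 <- intersect(group1, keep)
    group2 <- intersect(group2, keep)
    peaks <- peaks[, keep, drop = FALSE]
  }
  lnorm <- log_normalize(peaks)
  res <- row_welch(lnorm[, group2, drop = FALSE],
                   lnorm[, group1, drop = FALSE])
  q <- p.adjust(res$p, "BH")
  tab <- data.frame(peak = rownames(peaks), t = res$t, p = res$p, q = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, specific = tab$peak[tab$q < q_max & tab$t > 0])
}
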