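#' One-sided paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (classic convention); the exact null
#' distribution is used when the number of informative pairs is at most 25
#' and there are no tied absolute differences, otherwise the normal
#' approximation with continuity correction.
#'
#' @param pairs data.frame with `value_primary` and `value_recurrent`
#'   (one row per patient), or two numeric vectors via `y`.
#' @param alternative `"greater"` tests recurrent > primary; `"less"` the
#'   reverse.
#' @param y Optional second vector when `pairs` is a numeric vector of
#'   primary values.
#' @return List with `W` (signed-rank statistic of recurrent - primary),
#'   `p`, `n_informative`.
#' @export
paired_wilcoxon <- function(pairs, alternative = c("greater", "less"),
                            y = NULL) {
  alternative <- match.arg(alternative)
  if (is.data.frame(pairs)) {
    x <- pairs$value_recurrent
    ref <- pairs$value_primary
  } else {
    x <- y
    ref <- pairs
  }
  d <- x - ref
  d <- d[!is.na(d)]
  informative <- d[d != 0]
  n <- length(informative)
  if (n == 0) {
    warn_fmt("all paired differences are zero; p = 1")
    return(list(W = 0, p = 1, n_informative = 0L))
  }
  if (n < 5)
    warn_fmt("only %d informative pairs; signed-rank test is weak", n)
  ties <- anyDuplicated(abs(informative)) > 0
  ht <- suppressWarnings(
    wilcox.test(informative, alternative = alternative, mu = 0,
                exact = (n <= 25) && !ties, correct = TRUE))
  list(W = unname(ht$statistic), p = ht$p.value, n_informative = n)
}

#' One-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact when the combined sample size is at most 20 and tie-free,
#' otherwise normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y Numeric samples.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return List with `U` (Mann-Whitney statistic for x) and `p`.
#' @export
ranksum <- function(x, y, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop_fmt("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative,
                exact = (length(x) + length(y) <= 20) && !ties,
                correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' One-sided Fisher's exact test on a 2x2 table
#'
#' Hypergeometric tail probability for the stated direction. A zero row or
#' column margin gives p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"greater"` (enrichment of cell \[1,1\]) or
#'   `"less"`.
#' @return The one-sided p-value.
#' @export
fisher_2x2 <- function(table, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table %% 1 != 0))
    stop_fmt("table must hold non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  fisher.test(table, alternative = alternative)$p.value
}

#' Hypermutation call from tumor mutational burden
#'
#' Hypermutated iff TMB strictly exceeds 20 mutations per megabase.
#'
#' @param tmb Non-negative numeric vector (mutations/Mb).
#' @param cutoff Threshold (default 20).
#' @return Logical vector.
#' @export
call_hypermutation <- function(tmb, cutoff = 20) {
  if (any(tmb < 0)) stop_fmt("TMB must be non-negative")
  tmb > cutoff
}

#' Split samples into T-cell high and low groups
#'
#' High iff the T-cell percentage strictly exceeds the cutoff (default 1%).
#'
#' @param tcell_pct Percentages in \[0, 100\], named by sample.
#' @param cutoff Percent cutoff (default 1).
#' @return Named factor with levels `low`, `high`; group counts reported.
#' @export
split_tcell_groups <- function(tcell_pct, cutoff = 1.0) {
  if (any(tcell_pct < 0 | tcell_pct > 100))
    stop_fmt("percentages must lie in [0, 100]")
  g <- factor(ifelse(tcell_pct > cutoff, "high", "low"),
              levels = c("low", "high"))
  names(g) <- names(tcell_pct)
  message(sprintf("split_tcell_groups: %d low, %d high at %.3g%%",
                  sum(g == "low"), sum(g == "high"), cutoff))
  g
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimator per group with right-censoring and the standard
#' log-rank chi-squared (hypergeometric variance, handling ties).
#'
#' @param surv data.frame with `time_days` (> 0), `event` (0/1) and
#'   `group` (two non-empty levels).
#' @return List with `fit` (a `survfit`), `chisq`, `p`, `n_events`.
#' @export
km_logrank <- function(surv) {
  stopifnot(all(c("time_days", "event", "group") %in% names(surv)))
  if (any(surv$time_days <= 0)) stop_fmt("times must be positive")
  grp <- factor(surv$group)
  if (nlevels(droplevels(grp)) != 2)
    stop_fmt("survival comparison needs exactly 2 non-empty groups")
  n_events <- sum(surv$event)
  fit <- survival::survfit(survival::Surv(time_days, event) ~ group,
                           data = surv)
  if (n_events == 0) {
    warn_fmt("no events; log-rank p undefined")
    return(list(fit = fit, chisq = NA_real_, p = NA_real_, n_events = 0L))
  }
  if (n_events < 3)
    warn_fmt("only %d events; log-rank test is weak", n_events)
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ group,
                           data = surv)
  p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(fit = fit, chisq = unname(sd$chisq), p = p, n_events = n_events)
}

#' Ligand-receptor correlation across spatial ROIs
#'
#' Pearson correlation of ligand and receptor expression across regions of
#' interest, BH-adjusted across pairs. Pairs with a zero-variance gene get
#' r = NA and are excluded from the FDR.
#'
#' @param roi_matrix ROIs x genes matrix (>= 4 ROIs).
#' @param pairs data.frame with `ligand` and `receptor` columns.
#' @return data.frame `ligand`, `receptor`, `r`, `p`, `q`.
#' @export
lr_pair_correlation <- function(roi_matrix, pairs) {
  if (nrow(roi_matrix) < 4) stop_fmt("need >= 4 ROIs")
  n <- nrow(roi_matrix)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    lg <- pairs$ligand[i]; rc <- pairs$receptor[i]
    if (!lg %in% colnames(roi_matrix) || !rc %in% colnames(roi_matrix))
      return(c(NA_real_, NA_real_))
    a <- roi_matrix[, lg]; b <- roi_matrix[, rc]
    if (sd(a) == 0 || sd(b) == 0) return(c(NA_real_, NA_real_))
    r <- cor(a, b)
    t <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
    c(r, 2 * pt(abs(t), n - 2, lower.tail = FALSE))
  })
  r <- vapply(res, `[`, numeric(1), 1)
  p <- vapply(res, `[`, numeric(1), 2)
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- p.adjust(p[!is.na(p)], "BH")
  data.frame(ligand = pairs$ligand, receptor = pairs$receptor,
             r = r, p = p, q = q, stringsAsFactors = FALSE)
}

#' Cell-type communication scores with a permutation null
#'
#' For every sender type s, receiver type r and ligand-receptor pair, the
#' score is `mean expr(ligand | s) * mean expr(receptor | r)`; the null
#' distribution is obtained by shuffling cell-type labels, giving a
#' one-sided permutation p-value. A deliberately simple network statistic:
#' no subunit or antagonist logic.
#'
#' @param norm Genes x cells normalized matrix.
#' @param labels Named cell-type labels (>= 2 types, each >= 10 cells).
#' @param pairs data.frame with `ligand`, `receptor` (and optionally
#'   `pathway`); pairs with absent genes are skipped with a message.
#' @param n_perm Number of label permutations (default 500).
#' @param seed Seed.
#' @return data.frame `ligand`, `receptor`, `sender`, `receiver`,
#'   `score`, `p`.
#' @export
lr_network_score <- function(norm, labels, pairs, n_perm = 500, seed = 1L) {
  labels <- labels[colnames(norm)]
  types <- names(which(table(labels) >= 10))
  if (length(types) < 2)
    stop_fmt("need >= 2 cell types with >= 10 cells")
  keep <- labels %in% types
  norm <- norm[, keep, drop = FALSE]
  labels <- factor(labels[keep], levels = types)

  present <- pairs$ligand %in% rownames(norm) &
    pairs$receptor %in% rownames(norm)
  if (any(!present))
    message(sprintf("lr_network_score: skipping %d pairs with absent genes",
                    sum(!present)))
  pairs <- pairs[present, , drop = FALSE]
  genes <- unique(c(pairs$ligand, pairs$receptor))
  x <- as.matrix(norm[genes, , drop = FALSE])

  type_means <- function(lab) {
    t(rowsum(t(x), lab) / as.vector(table(lab)))
  }
  obs <- type_means(labels)
  grid <- expand.grid(pair = seq_len(nrow(pairs)), sender = types,
                      receiver = types, stringsAsFactors = FALSE)
  score_of <- function(tm) {
    tm[cbind(pairs$ligand[grid$pair], grid$sender)] *
      tm[cbind(pairs$receptor[grid$pair], grid$receiver)]
  }
  obs_score <- score_of(obs)
  exceed <- rep(0L, length(obs_score))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample(labels)
      exceed <- exceed + (score_of(type_means(perm)) >= obs_score)
    }
  })
  data.frame(ligand = pairs$ligand[grid$pair],
             receptor = pairs$receptor[grid$pair],
             sender = grid$sender, receiver = grid$receiver,
             score = obs_score, p = (exceed + 1) / (n_perm + 1),
             stringsAsFactors = FALSE)
}
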