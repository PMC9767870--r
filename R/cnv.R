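#' Per-cell expression score for a chromosome-arm region
#'
#' The region score of a cell is the mean, over the region's genes, of the
#' gene-centered normalized expression, minus the cell's baseline (the same
#' mean taken over all genes outside the region). The baseline term removes
#' the shared per-cell component that survives gene centering (library
#' depth interacts non-linearly with the log transform), which would
#' otherwise make every neutral arm look multimodal in large cohorts; the
#' dosage signal of the arm itself is untouched because the baseline
#' excludes the region's genes. Scores are centered: the cohort mean is ~0
#' for every region.
#'
#' @param norm Genes x cells normalized matrix.
#' @param annot Gene annotation data.frame with `gene_id` and `arm`.
#' @param region Arm name (e.g. `"7p"`).
#' @param min_genes Minimum region genes present in the matrix (default 20);
#'   smaller regions are skipped with a warning (returns NULL).
#' @param cohort_stats Optional precomputed whole-matrix centered column
#'   sums (internal; lets [cnv_scan()] avoid one full pass per region).
#' @return List of class `region_score` with `region` and named numeric
#'   `score`, or NULL if the region has too few measured genes.
#' @export
region_scores <- function(norm, annot, region, min_genes = 20,
                          cohort_stats = NULL) {
  if (!region %in% annot$arm)
    stop_fmt("region '%s' absent from annotation", region)
  g <- intersect(annot$gene_id[annot$arm == region], rownames(norm))
  if (length(g) < min_genes) {
    warn_fmt("region %s has %d genes (< %d); skipped", region, length(g),
             min_genes)
    return(NULL)
  }
  x <- norm[g, , drop = FALSE]
  rm_g <- row_means(x)
  cs_g <- as.numeric(col_sums(x)) - sum(rm_g)
  region_mean <- cs_g / length(g)
  n_other <- nrow(norm) - length(g)
  baseline <- if (n_other > 0) {
    cs_all <- cohort_stats %||%
      (as.numeric(col_sums(norm)) - sum(row_means(norm)))
    (cs_all - cs_g) / n_other
  } else 0
  score <- region_mean - baseline
  names(score) <- colnames(norm)
  structure(list(region = region, score = score), class = "region_score")
}

#' Fit a two-component equal-variance Gaussian mixture to region scores
#'
#' EM with multiple restarts (one deterministic quantile-based start plus
#' random starts), alongside the one-component maximum-likelihood fit.
#' Components are ordered so `mu1 <= mu2`. The likelihood-ratio statistic
#' `2 * (loglik2 - loglik1)` is referred to a chi-squared distribution with
#' 2 df; the BIC difference is the operative filter downstream. BIC is
#' `-2*loglik + k*log(n)` with k = 2 (one component: mean, sd) and k = 4
#' (two components: two means, shared sd, weight).
#'
#' @param score A `region_score` or numeric vector of per-cell scores.
#' @param n_restarts Number of EM starts (default 10).
#' @param tol Convergence tolerance on the log-likelihood change, relative
#'   to `1 + |loglik|` (default 1e-6).
#' @param max_iter Maximum EM iterations per start (default 500).
#' @param seed Seed for the random restarts.
#' @return List of class `mixture_fit`: `mu1`, `mu2`, `sigma`, `w`
#'   (weight of component 1), `loglik1`, `loglik2`, `bic1`, `bic2`,
#'   `lrt_p`, `n`, `region`.
#' @export
fit_mixture <- function(score, n_restarts = 10, tol = 1e-6, max_iter = 500,
                        seed = NULL) {
  region <- NA_character_
  if (inherits(score, "region_score")) {
    region <- score$region
    score <- score$score
  }
  x <- as.numeric(score)
  n <- length(x)
  if (n < 50) stop_fmt("fit_mixture requires >= 50 cells (got %d)", n)

  sigma_floor <- 1e-4
  mu0 <- mean(x)
  s0 <- max(sqrt(mean((x - mu0)^2)), sigma_floor)
  loglik1 <- sum(dnorm(x, mu0, s0, log = TRUE))

  em_once <- function(mu1, mu2, w, sigma) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- w * dnorm(x, mu1, sigma)
      d2 <- (1 - w) * dnorm(x, mu2, sigma)
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      # EM guarantees a non-decreasing likelihood; tolerate rounding only
      if (ll < ll_old - 1e-8)
        stop_fmt("EM log-likelihood decreased (%.6g -> %.6g)", ll_old, ll)
      # relative convergence: absolute tol is unattainable when |ll| is large
      if (is.finite(ll_old) && ll - ll_old < tol * (1 + abs(ll)))
        return(list(mu1 = mu1, mu2 = mu2, w = w, sigma = sigma, ll = ll,
                    converged = TRUE))
      ll_old <- ll
      r1 <- d1 / tot
      n1 <- sum(r1)
      n2 <- n - n1
      if (n1 < 1e-10 || n2 < 1e-10)
        return(list(mu1 = mu1, mu2 = mu2, w = w, sigma = sigma, ll = ll,
                    converged = TRUE))
      mu1 <- sum(r1 * x) / n1
      mu2 <- sum((1 - r1) * x) / n2
      sigma <- sqrt((sum(r1 * (x - mu1)^2) +
                       sum((1 - r1) * (x - mu2)^2)) / n)
      sigma <- max(sigma, sigma_floor)
      w <- n1 / n
    }
    list(mu1 = mu1, mu2 = mu2, w = w, sigma = sigma, ll = ll_old,
         converged = FALSE)
  }

  fits <- with_seed(seed, {
    starts <- list(list(mu1 = unname(quantile(x, 0.25)),
                        mu2 = unname(quantile(x, 0.75)),
                        w = 0.5, sigma = s0))
    if (n_restarts > 1) {
      for (r in seq_len(n_restarts - 1)) {
        ctr <- sort(sample(x, 2))
        starts[[r + 1]] <- list(mu1 = ctr[1], mu2 = ctr[2],
                                w = runif(1, 0.3, 0.7),
                                sigma = max(s0 * runif(1, 0.5, 1.5),
                                            sigma_floor))
      }
    }
    lapply(starts, function(s) em_once(s$mu1, s$mu2, s$w, s$sigma))
  })
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(conv))
    stop_fmt("EM failed to converge in all %d restarts (n = %d, sd = %.4g)",
             n_restarts, n, s0)
  lls <- vapply(fits, `[[`, numeric(1), "ll")
  lls[!conv] <- -Inf
  best <- fits[[which.max(lls)]]
  # the two-component family nests the one-component fit
  if (best$ll < loglik1)
    best <- list(mu1 = mu0, mu2 = mu0, w = 0.5, sigma = s0, ll = loglik1)
  if (best$mu1 > best$mu2)
    best <- list(mu1 = best$mu2, mu2 = best$mu1, w = 1 - best$w,
                 sigma = best$sigma, ll = best$ll)
  loglik2 <- best$ll
  lrt <- max(0, 2 * (loglik2 - loglik1))
  structure(list(
    region = region, mu1 = best$mu1, mu2 = best$mu2, sigma = best$sigma,
    w = best$w, loglik1 = loglik1, loglik2 = loglik2,
    bic1 = -2 * loglik1 + 2 * log(n), bic2 = -2 * loglik2 + 4 * log(n),
    lrt_p = pchisq(lrt, df = 2, lower.tail = FALSE), n = n),
    class = "mixture_fit")
}

#' Call CNV regions from mixture fits
#'
#' A region is retained when the two-component fit improves the BIC by more
#' than `dbic_min` (computed as `bic1 - bic2`, positive when two components
#' fit better) and the likelihood-ratio p-value is below `lrt_alpha`.
#'
#' @param fits Named list of `mixture_fit` objects (names are regions).
#' @param dbic_min Minimum BIC difference (default 50).
#' @param lrt_alpha LRT significance threshold (default 0.05).
#' @return Character vector of retained region names.
#' @export
call_regions <- function(fits, dbic_min = 50, lrt_alpha = 0.05) {
  if (!length(fits)) stop_fmt("no mixture fits supplied")
  keep <- vapply(fits, function(f)
    (f$bic1 - f$bic2) > dbic_min && f$lrt_p < lrt_alpha, logical(1))
  names(fits)[keep]
}

#' Assign per-cell CNV carrier status
#'
#' Identifies the CNV-carrying component of a called mixture — the
#' component holding the minority of `reference_cells` (e.g. known
#' non-malignant cells) when provided, otherwise the component with the
#' larger absolute mean — then flags carriers at posterior probability
#' > 0.5. Direction is `gain` when the CNV component mean exceeds the
#' other component's mean, `loss` otherwise.
#'
#' @param fit A `mixture_fit` that passed [call_regions()].
#' @param score The matching `region_score` (or numeric vector).
#' @param reference_cells Optional character vector of cell ids known to be
#'   CNV-free, used to orient the components.
#' @return List of class `cnv_call` with `region`, `direction`,
#'   `posterior` (per-cell probability of the CNV component), `carrier`
#'   (posterior > 0.5) and `frequency`.
#' @export
assign_cnv_status <- function(fit, score, reference_cells = NULL) {
  region <- fit$region
  if (inherits(score, "region_score")) score <- score$score
  x <- as.numeric(score)
  names(x) <- names(score)
  d1 <- fit$w * dnorm(x, fit$mu1, fit$sigma)
  d2 <- (1 - fit$w) * dnorm(x, fit$mu2, fit$sigma)
  tot <- d1 + d2
  tot[tot == 0] <- .Machine$double.xmin
  post1 <- d1 / tot
  names(post1) <- names(x)
  cnv_is_2 <- abs(fit$mu2) >= abs(fit$mu1)
  if (!is.null(reference_cells)) {
    ref <- intersect(reference_cells, names(x))
    if (length(ref)) {
      in1 <- mean(post1[ref] > 0.5)
      if (in1 == 0.5) {
        message("assign_cnv_status: reference cells split 50/50; ",
                "falling back to larger-|mean| rule")
      } else {
        cnv_is_2 <- in1 > 0.5 # reference (normal) cells mostly in comp 1
      }
    }
  }
  posterior <- if (cnv_is_2) 1 - post1 else post1
  names(posterior) <- names(score)
  mu_cnv <- if (cnv_is_2) fit$mu2 else fit$mu1
  mu_ref <- if (cnv_is_2) fit$mu1 else fit$mu2
  carrier <- posterior > 0.5
  structure(list(region = region,
                 direction = if (mu_cnv > mu_ref) "gain" else "loss",
                 posterior = posterior, carrier = carrier,
                 frequency = mean(carrier)),
            class = "cnv_call")
}

#' Classify cells as malignant by CNV carriage
#'
#' A cell is malignant when it carries at least one called CNV.
#'
#' @param calls List of `cnv_call` objects.
#' @param cell_ids Cell identifiers to classify.
#' @return Named logical vector.
#' @export
classify_malignant <- function(calls, cell_ids) {
  out <- setNames(rep(FALSE, length(cell_ids)), cell_ids)
  if (!length(calls)) {
    warn_fmt("no called CNV regions; all cells labelled non-malignant")
    return(out)
  }
  for (cl in calls) {
    carriers <- names(cl$carrier)[cl$carrier]
    out[intersect(carriers, cell_ids)] <- TRUE
  }
  out
}

#' Scan all arms for CNVs
#'
#' Convenience wrapper: scores every arm with enough measured genes, fits
#' the mixtures, calls regions at the BIC/LRT thresholds and assigns
#' per-cell carrier status for called regions.
#'
#' @param norm Genes x cells normalized matrix.
#' @param annot Gene annotation with `gene_id` and `arm`.
#' @param regions Arms to test (default: all arms in the annotation).
#' @param min_genes,dbic_min,lrt_alpha,n_restarts See the underlying
#'   functions.
#' @param reference_cells Optional CNV-free reference cell ids.
#' @param seed Seed for EM restarts.
#' @return List with `scores`, `fits`, `called` (region names), `calls`
#'   (list of `cnv_call`) and `malignant` (per-cell logical).
#' @export
cnv_scan <- function(norm, annot, regions = NULL, min_genes = 20,
                     dbic_min = 50, lrt_alpha = 0.05, n_restarts = 10,
                     reference_cells = NULL, seed = 1L) {
  regions <- regions %||% unique(annot$arm)
  cs_all <- as.numeric(col_sums(norm)) - sum(row_means(norm))
  scores <- list()
  for (r in regions) {
    rs <- suppressWarnings(region_scores(norm, annot, r, min_genes,
                                         cohort_stats = cs_all))
    if (!is.null(rs)) scores[[r]] <- rs
  }
  fits <- lapply(seq_along(scores), function(i)
    fit_mixture(scores[[i]], n_restarts = n_restarts, seed = seed + i))
  names(fits) <- names(scores)
  called <- call_regions(fits, dbic_min, lrt_alpha)
  calls <- lapply(called, function(r)
    assign_cnv_status(fits[[r]], scores[[r]], reference_cells))
  names(calls) <- called
  malignant <- if (length(calls)) classify_malignant(calls, colnames(norm))
  else suppressWarnings(classify_malignant(list(), colnames(norm)))
  list(scores = scores, fits = fits, called = called, calls = calls,
       malignant = malignant)
}

#' Summarize CNV calls as a table
#' @param scan Result of [cnv_scan()].
#' @return data.frame with region, direction, delta BIC, LRT p, frequency.
#' @export
cnv_call_table <- function(scan) {
  if (!length(scan$calls))
    return(data.frame(region = character(), direction = character(),
                      dbic = numeric(), lrt_p = numeric(),
                      frequency = numeric()))
  do.call(rbind, lapply(scan$calls, function(cl) {
    f <- scan$fits[[cl$region]]
    data.frame(region = cl$region, direction = cl$direction,
               dbic = f$bic1 - f$bic2, lrt_p = f$lrt_p,
               frequency = cl$frequency, stringsAsFactors = FALSE)
  }))
}

#' @importFrom stats setNames
NULL
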