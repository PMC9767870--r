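#' Storey q-values with BH fallback
#'
#' Estimates the null proportion pi0 on a lambda grid (0.05..0.95) with a
#' cubic-spline smoother evaluated at the largest lambda, then converts
#' BH-adjusted p-values to q-values by scaling with pi0. Falls back to
#' plain Benjamini-Hochberg when there are fewer than `min_features`
#' p-values or the pi0 estimate is unstable (outside (0, 1]); the method
#' used is recorded in the `"method"` attribute.
#'
#' @param p Numeric vector of p-values.
#' @param lambda Lambda grid.
#' @param min_features Minimum number of features for the Storey estimate
#'   (default 50).
#' @return Numeric vector of q-values with attributes `method` and `pi0`.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                          min_features = 50) {
  ok <- !is.na(p)
  m <- sum(ok)
  bh <- p.adjust(p, method = "BH")
  if (m < min_features) {
    attr(bh, "method") <- "BH"
    attr(bh, "pi0") <- 1
    return(bh)
  }
  pi0_lambda <- vapply(lambda, function(l) mean(p[ok] > l) / (1 - l),
                       numeric(1))
  pi0 <- tryCatch({
    fit <- smooth.spline(lambda, pi0_lambda, df = 3)
    predict(fit, x = max(lambda))$y
  }, error = function(e) NA_real_)
  if (is.na(pi0) || pi0 <= 0 || pi0 > 1) {
    attr(bh, "method") <- "BH"
    attr(bh, "pi0") <- 1
    return(bh)
  }
  q <- pmin(bh * pi0, 1)
  attr(q, "method") <- "storey"
  attr(q, "pi0") <- pi0
  q
}
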