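#' @importFrom methods as is
#' @importFrom stats rnbinom rpois rlnorm runif rnorm rbinom rexp
#'   pchisq pt sd var quantile cor dnorm kmeans hclust cutree as.dist
#'   prcomp p.adjust wilcox.test fisher.test smooth.spline predict
#'   rmultinom aggregate
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Row means / variances that work for base and Matrix matrices.
row_means <- function(x) {
  if (is(x, "Matrix")) Matrix::rowMeans(x) else rowMeans(x)
}

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(0, nrow(x)))
  mu <- row_means(x)
  if (is(x, "Matrix")) {
    (Matrix::rowSums(x^2) - n * mu^2) / (n - 1)
  } else {
    (rowSums(x^2) - n * mu^2) / (n - 1)
  }
}

col_sums <- function(x) {
  if (is(x, "Matrix")) Matrix::colSums(x) else colSums(x)
}

col_means <- function(x) {
  if (is(x, "Matrix")) Matrix::colMeans(x) else colMeans(x)
}

# Equal-occupancy binning by rank; returns integer bin ids in 1..n_bins.
rank_bins <- function(x, n_bins) {
  n_bins <- max(1L, min(as.integer(n_bins), length(x)))
  if (n_bins == 1L) return(rep(1L, length(x)))
  as.integer(cut(rank(x, ties.method = "first"),
                 breaks = n_bins, labels = FALSE))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
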