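# Independent oracles used to validate the package implementations.
# These deliberately use naive/enumerative algorithms.

# Grid-search maximum likelihood for the equal-variance 2-component
# Gaussian mixture: exhaustive over a quantile grid of means, a weight
# grid and a sd grid.
grid_mixture_oracle <- function(x, n_mu = 13, n_w = 7, n_sigma = 8) {
  mus <- unname(quantile(x, seq(0.02, 0.98, length.out = n_mu)))
  ws <- seq(0.1, 0.9, length.out = n_w)
  s0 <- sd(x)
  sigmas <- s0 * seq(0.3, 1.5, length.out = n_sigma)
  best <- -Inf
  for (s in sigmas) {
    d <- vapply(mus, function(m) dnorm(x, m, s), numeric(length(x)))
    for (i in seq_len(n_mu)) for (j in i:n_mu) for (w in ws) {
      ll <- sum(log(w * d[, i] + (1 - w) * d[, j]))
      if (ll > best) best <- ll
    }
  }
  best
}

# Naive both-strand PWM scan: explicit loops, no vectorization.
brute_pwm_scan <- function(sequence, pwm, score_min) {
  bases <- c("A", "C", "G", "T")
  lo <- log2(pwm$prob / pwm$background)
  w <- ncol(pwm$prob)
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  hits <- list()
  if (L >= w) {
    for (start0 in 0:(L - w)) {
      win <- chars[(start0 + 1):(start0 + w)]
      if (any(!win %in% bases)) next
      # forward strand
      sc <- 0
      for (j in seq_len(w)) sc <- sc + lo[win[j], j]
      if (sc >= score_min)
        hits[[length(hits) + 1]] <- data.frame(start = start0, strand = "+",
                                               score = sc)
      # reverse strand: motif on the minus strand over the same window
      rcwin <- rev(unname(comp[win]))
      sc <- 0
      for (j in seq_len(w)) sc <- sc + lo[rcwin[j], j]
      if (sc >= score_min)
        hits[[length(hits) + 1]] <- data.frame(start = start0, strand = "-",
                                               score = sc)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out$strand <- as.character(out$strand)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Exact one-sided signed-rank p by enumerating all 2^n sign patterns.
enum_signed_rank <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- signs %*% r
  if (alternative == "greater") mean(W_all >= W_obs) else
    mean(W_all <= W_obs)
}

# Exact one-sided rank-sum p by enumerating all group assignments.
enum_ranksum <- function(x, y, alternative = "greater") {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- combn(length(pooled), m)
  U_all <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  if (alternative == "greater") mean(U_all >= U_obs) else
    mean(U_all <= U_obs)
}

# Direct O-E / hypergeometric-variance log-rank chi-squared.
logrank_oracle <- function(time, event, group) {
  group <- as.integer(factor(group))
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# One-sided Fisher p by direct hypergeometric summation.
fisher_oracle <- function(tab, alternative = "greater") {
  a <- tab[1, 1]
  m <- sum(tab[1, ]) # margin of row 1
  k <- sum(tab[, 1]) # margin of col 1
  n <- sum(tab)
  lo <- max(0, k + m - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n - m, k)
  if (alternative == "greater") sum(probs[(lo:hi) >= a]) else
    sum(probs[(lo:hi) <= a])
}

# Adjusted Rand index for comparing clusterings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
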