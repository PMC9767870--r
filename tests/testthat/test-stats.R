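test_that("signed-rank p-values match exact enumeration", {
  # all-positive differences, n = 6: p = 1/64
  tab <- data.frame(value_primary = rep(0, 6),
                    value_recurrent = c(1, 2, 5, 4, 3, 6))
  out <- paired_wilcoxon(tab, "greater")
  expect_equal(out$p, 1 / 64)
  expect_equal(out$W, 21)
  # identical pairs: p = 1 with a warning
  same <- data.frame(value_primary = 1:5, value_recurrent = 1:5)
  expect_warning(res <- paired_wilcoxon(same, "greater"), "zero")
  expect_equal(res$p, 1)
  # random tie-free cases agree with the 2^n enumeration oracle
  set.seed(6)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    d <- round(rnorm(n, 0.3), 3)
    d <- d[d != 0]
    alt <- sample(c("greater", "less"), 1)
    got <- paired_wilcoxon(data.frame(value_primary = 0,
                                      value_recurrent = d), alt)
    expect_equal(got$p, enum_signed_rank(d, alt))
  }
  # exact-test complement relation
  d <- c(1.2, -0.4, 0.8, 2.2, -1.5, 0.3)
  pg <- paired_wilcoxon(data.frame(value_primary = 0,
                                   value_recurrent = d), "greater")$p
  pl <- paired_wilcoxon(data.frame(value_primary = 0,
                                   value_recurrent = d), "less")$p
  expect_gte(pg + pl, 1)
})

test_that("rank-sum p-values match exact enumeration", {
  out <- ranksum(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(out$p, 1 / 20)
  expect_equal(out$U, 0)
  # identical multisets are not significant
  expect_gte(ranksum(c(1, 2, 3), c(1, 2, 3), "greater")$p, 0.5)
  # random tie-free cases agree with the C(m+n, m) enumeration oracle
  set.seed(7)
  for (i in 1:10) {
    x <- round(rnorm(sample(3:6, 1)), 3)
    y <- round(rnorm(sample(3:6, 1), 0.5), 3)
    alt <- sample(c("greater", "less"), 1)
    expect_equal(ranksum(x, y, alt)$p, enum_ranksum(x, y, alt))
  }
})

test_that("Fisher one-sided p equals hypergeometric summation", {
  sep <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(fisher_2x2(sep, "greater"), 1 / choose(20, 10),
               tolerance = 1e-12)
  expect_gt(fisher_2x2(matrix(c(5, 5, 5, 5), 2, 2), "greater"), 0.5)
  expect_equal(fisher_2x2(matrix(c(0, 3, 0, 4), 2, 2), "greater"), 1)
  set.seed(8)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    for (alt in c("greater", "less"))
      expect_equal(fisher_2x2(tab, alt), fisher_oracle(tab, alt),
                   tolerance = 1e-12)
  }
})

test_that("hypermutation and T-cell splits use strict thresholds", {
  expect_identical(call_hypermutation(c(20, 20.1, 0, 35)),
                   c(FALSE, TRUE, FALSE, TRUE))
  expect_error(call_hypermutation(-1), "non-negative")
  g <- suppressMessages(split_tcell_groups(c(a = 1.0, b = 2.5, c = 0.2)))
  expect_identical(as.character(g), c("low", "high", "low"))
  expect_error(split_tcell_groups(c(150)), "0, 100")
  # empty group: the survival comparison refuses
  surv <- data.frame(time_days = c(10, 20, 30), event = 1,
                     group = "low")
  expect_error(km_logrank(surv), "2 non-empty groups")
})

test_that("log-rank matches the direct O-E computation and KM the empirical curve", {
  surv <- data.frame(time_days = c(1, 2, 3, 4, 5, 6), event = 1,
                     group = rep(c("A", "B"), each = 3))
  out <- km_logrank(surv)
  oracle <- logrank_oracle(surv$time_days, surv$event, surv$group)
  expect_equal(out$chisq, oracle$chisq, tolerance = 1e-9)
  expect_equal(out$p, oracle$p, tolerance = 1e-9)

  # identical event times in both groups: chisq 0, p 1
  tie <- data.frame(time_days = rep(c(5, 10, 15), 2), event = 1,
                    group = rep(c("A", "B"), each = 3))
  out_tie <- km_logrank(tie)
  expect_equal(out_tie$chisq, 0, tolerance = 1e-12)
  expect_equal(out_tie$p, 1)

  # without censoring the product-limit estimate is the empirical survival
  set.seed(9)
  t1 <- sort(sample(1:100, 8))
  km <- km_logrank(data.frame(time_days = c(t1, 1:8), event = 1,
                              group = rep(c("A", "B"), each = 8)))
  sf <- summary(km$fit)
  sA <- sf$surv[sf$strata == "group=A"]
  expect_equal(sA, 1 - seq_len(8) / 8, tolerance = 1e-12)

  # no events: NA p with warning
  none <- data.frame(time_days = c(3, 4, 5, 6), event = 0,
                     group = rep(c("A", "B"), 2))
  expect_warning(out0 <- km_logrank(none), "no events")
  expect_true(is.na(out0$p))
})

test_that("row order never changes a test decision", {
  set.seed(10)
  tab <- data.frame(value_primary = rnorm(12), value_recurrent = rnorm(12, 1))
  perm <- sample(12)
  expect_equal(paired_wilcoxon(tab, "greater"),
               paired_wilcoxon(tab[perm, ], "greater"))
  x <- rnorm(9); y <- rnorm(11, 0.4)
  expect_equal(ranksum(x, y, "less"), ranksum(sample(x), sample(y), "less"))
})

test_that("spatial ligand-receptor correlations behave at the limits", {
  mat <- cbind(L1 = c(1, 2, 3, 4, 5), R1 = c(2, 4, 6, 8, 10),
               L2 = c(1, 3, 2, 5, 4), R2 = rep(2, 5))
  rownames(mat) <- sprintf("roi%d", 1:5)
  pairs <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"))
  res <- lr_pair_correlation(mat, pairs)
  expect_equal(res$r[1], 1)
  expect_true(is.na(res$r[2])) # constant receptor
  expect_true(is.na(res$q[2])) # excluded from the FDR
  expect_error(lr_pair_correlation(mat[1:3, ], pairs), ">= 4")
})

test_that("communication scores localize exclusive ligand-receptor pairs", {
  set.seed(11)
  genes <- c("LIG", "REC", sprintf("bg%d", 1:20))
  cells <- sprintf("c%d", 1:90)
  x <- matrix(rexp(length(genes) * 90, 2), length(genes), 90,
              dimnames = list(genes, cells))
  labels <- rep(c("A", "B", "C"), each = 30)
  names(labels) <- cells
  x["LIG", ] <- ifelse(labels == "A", 3, 0)
  x["REC", ] <- ifelse(labels == "B", 3, 0)
  pairs <- data.frame(ligand = "LIG", receptor = "REC")
  res <- lr_network_score(x, labels, pairs, n_perm = 100, seed = 12)
  nz <- res[res$score > 0, ]
  expect_equal(nrow(nz), 1)
  expect_identical(nz$sender, "A")
  expect_identical(nz$receiver, "B")
  expect_lt(nz$p, 0.05)
  # absent genes are skipped with a message
  pairs2 <- rbind(pairs, data.frame(ligand = "nope", receptor = "REC"))
  expect_message(lr_network_score(x, labels, pairs2, n_perm = 10, seed = 1),
                 "skipping")
})
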