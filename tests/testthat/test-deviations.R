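sim_peaks <- function(n_peaks, n_cells, seed = 1, lambda = 2) {
  set.seed(seed)
  m <- matrix(rpois(n_peaks * n_cells, lambda), n_peaks, n_cells,
              dimnames = list(sprintf("pk%d", seq_len(n_peaks)),
                              sprintf("c%d", seq_len(n_cells))))
  m
}

test_that("background sets are bin-matched and reproducible", {
  pk <- sim_peaks(200, 50, seed = 2)
  gc <- runif(200, 0.3, 0.7)
  bg <- background_peak_sets(pk, gc, n_sets = 20, seed = 7)
  expect_identical(bg, background_peak_sets(pk, gc, n_sets = 20, seed = 7))
  # a planted GC gradient: background peaks stay inside the foreground bin
  gc_sorted <- sort(gc)
  bg2 <- background_peak_sets(pk, gc_sorted, n_sets = 10, n_bins_gc = 10,
                              n_bins_acc = 1, seed = 3)
  bin_of <- as.integer(cut(rank(gc_sorted, ties.method = "first"), 10,
                           labels = FALSE))
  for (s in 1:10)
    expect_true(all(bin_of[bg2[, s]] == bin_of))
  # identical GC and accessibility: one bin, uniform resampling
  pk_flat <- matrix(2L, 50, 10,
                    dimnames = list(sprintf("p%d", 1:50), NULL))
  bg3 <- background_peak_sets(pk_flat, rep(0.5, 50), n_sets = 5, seed = 1)
  expect_true(all(bg3 >= 1 & bg3 <= 50))
})

test_that("deviations vanish for the all-peaks motif and track planted shifts", {
  pk <- sim_peaks(100, 60, seed = 4)
  gc <- runif(100, 0.4, 0.6)
  bg <- background_peak_sets(pk, gc, n_sets = 30, seed = 5)
  dev <- compute_deviations(pk, list(all = rownames(pk)), bg)
  expect_true(all(attr(dev, "raw")["all", ] == 0))
  expect_true(all(dev["all", ] == 0))

  # doubling member-peak counts in one cell group drives positive z there
  pk2 <- sim_peaks(20, 40, seed = 6, lambda = 5)
  members <- rownames(pk2)[1:6]
  grp <- 1:20
  pk2[members, grp] <- pk2[members, grp] * 2L
  gc2 <- runif(20, 0.4, 0.6)
  bg2 <- background_peak_sets(pk2, gc2, n_sets = 30, seed = 8)
  dev2 <- compute_deviations(pk2, list(m = members), bg2)
  expect_gt(mean(dev2["m", grp]), mean(dev2["m", -grp]))
  # hand-computed raw deviation for the first cell
  X <- sum(pk2[members, 1])
  E <- sum(rowSums(pk2)[members]) / sum(pk2) * sum(pk2[, 1])
  expect_equal(attr(dev2, "raw")["m", 1], (X - E) / E)
})

test_that("structure-free accessibility yields vanishing deviations", {
  # structure-free: every cell's accessibility is proportional to the peak
  # totals, so observed always equals expected
  set.seed(9)
  peak_w <- rlnorm(400, 0, 1)
  depth <- rlnorm(150, 0, 0.4)
  pk <- outer(peak_w, depth)
  dimnames(pk) <- list(sprintf("pk%d", 1:400), sprintf("c%d", 1:150))
  gc <- runif(400, 0.3, 0.7)
  bg <- background_peak_sets(pk, gc, n_sets = 50, seed = 10)
  set.seed(11)
  membership <- list(a = sample(rownames(pk), 60),
                     b = sample(rownames(pk), 40))
  dev <- compute_deviations(pk, membership, bg)
  expect_lt(mean(abs(dev)), 0.2)
  expect_lt(max(abs(attr(dev, "raw"))), 1e-10)
  # with count noise around the proportional means, z stays centered
  pk2 <- matrix(rpois(length(pk), pk), nrow(pk), ncol(pk),
                dimnames = dimnames(pk))
  bg2 <- background_peak_sets(pk2, gc, n_sets = 50, seed = 12)
  dev2 <- compute_deviations(pk2, membership, bg2)
  expect_lt(abs(mean(dev2)), 0.3)
  expect_true(all(is.finite(dev2)))
})

test_that("differential deviations flag planted shifts and respect edge cases", {
  set.seed(12)
  dev <- matrix(rnorm(50 * 60), 50, 60,
                dimnames = list(sprintf("m%d", 1:50),
                                sprintf("c%d", 1:60)))
  g1 <- sprintf("c%d", 1:30)
  g2 <- sprintf("c%d", 31:60)
  dev["m1", g2] <- dev["m1", g2] + 2
  res <- differential_deviations(dev, g1, g2)
  expect_lt(res$q[res$motif == "m1"], 0.05)
  # single motif: q equals p
  res1 <- differential_deviations(dev["m1", , drop = FALSE], g1, g2)
  expect_equal(res1$q, res1$p)
  # zero-variance motif: p = 1
  dev["m2", ] <- 3
  res2 <- differential_deviations(dev, g1, g2)
  expect_equal(res2$p[res2$motif == "m2"], 1)
  expect_error(differential_deviations(dev, g1[1:2], g2), ">= 3")
})

test_that("motif-profile clustering recovers planted usage groups", {
  set.seed(13)
  base <- matrix(rnorm(30 * 80, sd = 0.3), 30, 80)
  sig <- rnorm(30)
  base[, 1:40] <- base[, 1:40] + sig # shared program in group 1
  base[, 41:80] <- base[, 41:80] - sig
  colnames(base) <- sprintf("c%d", 1:80)
  rownames(base) <- sprintf("m%d", 1:30)
  out <- cluster_motif_profiles(base)
  expect_equal(adjusted_rand(out$clusters, rep(1:2, each = 40)), 1)
  expect_true(all(out$median_within > out$median_between))
  # i.i.d. profiles: within and between medians both near zero
  iid <- matrix(rnorm(30 * 60), 30, 60,
                dimnames = list(sprintf("m%d", 1:30), sprintf("c%d", 1:60)))
  out2 <- cluster_motif_profiles(iid)
  expect_lt(max(abs(c(out2$median_within, out2$median_between)),
                na.rm = TRUE), 0.25)
  # constant cells are dropped with a message
  iid[, 1] <- 2
  expect_message(cluster_motif_profiles(iid), "constant")
})
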