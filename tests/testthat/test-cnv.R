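toy_annot <- function(n_regions = 2, genes_per = 25) {
  do.call(rbind, lapply(seq_len(n_regions), function(i)
    data.frame(gene_id = sprintf("r%dg%d", i, seq_len(genes_per)),
               chromosome = sprintf("chr%d", i), arm = sprintf("%dp", i),
               start = seq_len(genes_per) * 100,
               end = seq_len(genes_per) * 100 + 50)))
}

test_that("region scores are centered and linear in planted shifts", {
  annot <- toy_annot()
  set.seed(1)
  norm <- toy_norm(rep(1.5, 50 * 40), 50, 40,
                   genes = annot$gene_id)
  # identical cells: all scores zero
  rs <- region_scores(norm, annot, "1p")
  expect_equal(unname(rs$score), rep(0, 40))
  # raise every region gene in one cell by delta: its score is delta
  delta <- 0.7
  norm2 <- norm
  norm2[annot$gene_id[annot$arm == "1p"], 5] <-
    norm2[annot$gene_id[annot$arm == "1p"], 5] + delta
  rs2 <- region_scores(norm2, annot, "1p")
  expect_equal(unname(rs2$score[5] - mean(rs2$score[-5])), delta,
               tolerance = 1e-10)
  # cohort centering invariant
  expect_lt(abs(mean(rs2$score)), 1e-10)
  # unknown region errors; small region skipped with warning
  expect_error(region_scores(norm, annot, "9q"), "absent")
  expect_warning(out <- region_scores(norm, annot, "1p", min_genes = 30),
                 "skipped")
  expect_null(out)
})

test_that("EM mixture fitting recovers parameters and stays monotone", {
  set.seed(11)
  x <- c(rnorm(250, -0.3, 0.12), rnorm(250, 0.3, 0.12))
  f <- fit_mixture(x, seed = 2)
  expect_lt(abs((f$mu2 - f$mu1) - 0.6), 0.05)
  expect_gte(f$loglik2, f$loglik1)
  expect_equal(f$bic1, -2 * f$loglik1 + 2 * log(500))
  expect_equal(f$bic2, -2 * f$loglik2 + 4 * log(500))
  expect_true(f$lrt_p >= 0 && f$lrt_p <= 1)
  # beats the exhaustive grid-search oracle
  expect_gte(f$loglik2, grid_mixture_oracle(x) - 1e-3)
  # cross-check against an independent EM implementation
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  mc <- mclust::Mclust(x, G = 2, modelNames = "E", verbose = FALSE)
  expect_lt(abs(f$loglik2 - mc$loglik), 0.05)
  expect_equal(sort(c(f$mu1, f$mu2)), sort(unname(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("degenerate and negated scores are handled symmetrically", {
  # constant vector: sigma floored, region rejected downstream
  f0 <- fit_mixture(rep(0.2, 100), seed = 1)
  expect_gte(f0$sigma, 1e-4)
  expect_identical(call_regions(list(const = f0)), character(0))
  expect_error(fit_mixture(rnorm(10)), ">= 50 cells")

  # negating scores swaps gain/loss but keeps the carrier set
  set.seed(3)
  x <- c(rnorm(300, 0, 0.1), rnorm(200, 0.4, 0.1))
  names(x) <- sprintf("c%d", seq_along(x))
  f_pos <- fit_mixture(x, seed = 9)
  f_neg <- fit_mixture(-x, seed = 9)
  call_pos <- assign_cnv_status(f_pos, x)
  call_neg <- assign_cnv_status(f_neg, -x)
  expect_identical(call_pos$direction, "gain")
  expect_identical(call_neg$direction, "loss")
  expect_identical(call_pos$carrier, call_neg$carrier)
})

test_that("region calling applies the strict dual threshold", {
  mk_fit <- function(dbic, p) {
    n <- 500
    ll1 <- -100
    structure(list(region = "x", mu1 = 0, mu2 = 1, sigma = 0.1, w = 0.5,
                   loglik1 = ll1, bic1 = -2 * ll1 + 2 * log(n),
                   loglik2 = ll1 + 50,
                   bic2 = -2 * ll1 + 2 * log(n) - dbic,
                   lrt_p = p, n = n), class = "mixture_fit")
  }
  expect_identical(call_regions(list(a = mk_fit(49.9, 0.001))), character(0))
  expect_identical(call_regions(list(a = mk_fit(120, 1e-12))), "a")
  expect_identical(call_regions(list(a = mk_fit(120, 0.06))), character(0))
  expect_error(call_regions(list()), "no mixture fits")
})

test_that("carrier assignment respects the posterior boundary and references", {
  f <- structure(list(region = "7p", mu1 = 0, mu2 = 0.4, sigma = 0.1,
                      w = 0.5, loglik1 = 0, loglik2 = 0, bic1 = 0,
                      bic2 = 0, lrt_p = 0, n = 100), class = "mixture_fit")
  # equal-responsibility point: posterior exactly 0.5 -> non-carrier
  x <- c(a = 0.2, b = 0.39, c = 0.01)
  cl <- assign_cnv_status(f, x)
  expect_equal(unname(cl$posterior["a"]), 0.5)
  expect_false(cl$carrier[["a"]])
  expect_true(cl$carrier[["b"]])
  expect_identical(cl$direction, "gain")
  expect_equal(cl$frequency, mean(cl$posterior > 0.5))
  # reference cells orient the components: normal component holds them
  cl_ref <- assign_cnv_status(f, x, reference_cells = c("b"))
  # reference cell b sits in the high component -> CNV is the low one
  expect_identical(cl_ref$direction, "loss")
  expect_true(cl_ref$carrier[["c"]])
  expect_false(cl_ref$carrier[["b"]])
})

test_that("malignant classification is the union of called carriers", {
  cl1 <- structure(list(region = "10q", direction = "loss",
                        posterior = c(a = 0.9, b = 0.1),
                        carrier = c(a = TRUE, b = FALSE), frequency = 0.5),
                   class = "cnv_call")
  out <- classify_malignant(list(cl1), c("a", "b", "c"))
  expect_identical(out, c(a = TRUE, b = FALSE, c = FALSE))
  expect_warning(out0 <- classify_malignant(list(), c("a", "b")),
                 "non-malignant")
  expect_false(any(out0))
})
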