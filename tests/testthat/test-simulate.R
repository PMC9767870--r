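test_that("cohort generation is deterministic under a fixed seed", {
  a <- small_cohort(seed = 3)
  b <- small_cohort(seed = 3)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$cell, b$truth$cell)
  expect_identical(a$sample_meta, b$sample_meta)
  c <- small_cohort(seed = 4)
  expect_false(identical(a$counts, c$counts))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(immune_mix = list(
    primary = c(malignant = 0.5, oligodendrocyte = 0.2, microglia = 0.1,
                bmdm = 0.1, tcell = 0.05), # sums to 0.95
    recurrent = c(malignant = 0.45, oligodendrocyte = 0.245,
                  microglia = 0.12, bmdm = 0.18, tcell = 0.005))),
    "sums to")
  expect_error(cohort_config(cnv_events = data.frame(
    arm = "7p", direction = "gain", fold = -1, malignant_fraction = 0.8,
    stages = "both")), "positive")
  expect_error(cohort_config(cnv_events = data.frame(
    arm = "99z", direction = "gain", fold = 1.3, malignant_fraction = 0.8,
    stages = "both")), "unknown arms")
})

test_that("emitted compositions converge to configured fractions", {
  co <- generate_cohort(cohort_config(n_patients = 1,
                                      cells_per_sample = 4000, seed = 9))
  cfg <- co$config
  for (stage in c("primary", "recurrent")) {
    cells <- co$truth$cell[co$truth$cell$stage == stage, ]
    sm <- co$truth$sample[co$truth$sample$stage == stage, ]
    comp <- cfg$immune_mix[[stage]]
    comp["tcell"] <- sm$tcell_frac
    others <- setdiff(names(comp), "tcell")
    comp[others] <- cfg$immune_mix[[stage]][others] *
      (1 - sm$tcell_frac) / sum(cfg$immune_mix[[stage]][others])
    for (ty in names(comp)) {
      obs <- mean(cells$cell_type == ty)
      # 4 sd multinomial bound
      tol <- 4 * sqrt(comp[[ty]] * (1 - comp[[ty]]) / nrow(cells)) + 1e-9
      expect_lt(abs(obs - comp[[ty]]), max(tol, 0.01))
    }
  }
})

test_that("planted CNVs shift carrier expression by about the dosage fold", {
  # low-noise variant: tight dispersion, no library-size variation
  co <- generate_cohort(cohort_config(
    n_patients = 2, cells_per_sample = 400, nb_dispersion = 0.02,
    cell_sdlog = 0, patient_sdlog = 0, seed = 5))
  tr <- co$truth
  for (ei in seq_len(nrow(tr$cnv_events))) {
    ev <- tr$cnv_events[ei, ]
    genes <- co$annotation$gene_id[co$annotation$arm == ev$arm]
    carr <- rownames(tr$carriers)[tr$carriers[, ev$arm]]
    noncar <- setdiff(tr$cell$cell_id[!tr$cell$malignant],
                      carr)
    ratio <- mean(co$counts[genes, carr]) / mean(co$counts[genes, noncar])
    expect_lt(abs(ratio - ev$fold), 0.05 * ev$fold)
  }
})

test_that("per-sample MES fraction rises by the configured amount", {
  # paired design at the cohort scale: 31 patients as in the study
  co <- generate_cohort(cohort_config(n_patients = 31,
                                      cells_per_sample = 300, seed = 21))
  tr <- co$truth$cell[co$truth$cell$malignant, ]
  mes_pct <- tapply(tr$phenotype == "MES",
                    paste(tr$patient_id, tr$stage), mean) * 100
  pats <- unique(tr$patient_id)
  shift <- mean(mes_pct[paste(pats, "recurrent")] -
                  mes_pct[paste(pats, "primary")])
  expect_lt(abs(shift - 20), 3)
})

test_that("sequences embed the consensus exactly where flagged", {
  truth <- data.frame(peak_id = sprintf("p%d", 1:40),
                      motif_ap1 = rep(c(TRUE, FALSE), 20))
  seqs <- generate_sequences(truth, peak_length = 120, seed = 8)
  ap1 <- pwm_from_consensus()
  thr <- 0.95 * pwm_max_score(ap1)
  rc <- "TGAGTCA"
  for (i in seq_len(40)) {
    fwd <- grepl("TGACTCA", seqs[i], fixed = TRUE)
    rev <- grepl(rc, seqs[i], fixed = TRUE)
    if (truth$motif_ap1[i]) {
      expect_gte(nrow(scan_pwm(seqs[[i]], ap1, thr)), 1)
    } else {
      expect_false(fwd || rev)
    }
  }
  emb <- attr(seqs, "embedding")
  bear <- which(truth$motif_ap1)
  expect_true(all(!is.na(emb$offset[bear])))
  # recorded offsets point at an actual consensus occurrence
  for (i in bear) {
    o <- emb$offset[i]
    win <- substr(seqs[[i]], o + 1, o + 7)
    expect_true(win == "TGACTCA" || win == rc)
  }
  # byte-identical reproduction
  expect_identical(seqs, generate_sequences(truth, peak_length = 120,
                                            seed = 8))
})

test_that("spatial fixture produces the configured gradient structure", {
  co <- small_cohort(seed = 2)
  # no noise: planted pairs correlate perfectly
  sp0 <- generate_spatial(co, noise_sd = 0, seed = 4)
  for (i in seq_len(nrow(sp0$lr_truth)))
    expect_equal(cor(sp0$mat[, sp0$lr_truth$ligand[i]],
                     sp0$mat[, sp0$lr_truth$receptor[i]]), 1)
  # zero gradient effect: expected correlation ~0 for all pairs
  spnull <- generate_spatial(co, gradient_effect = 0, n_rois = 200,
                             seed = 5)
  pairs <- co$config$lr_pairs
  rs <- vapply(seq_len(nrow(pairs)), function(i)
    cor(spnull$mat[, pairs$ligand[i]], spnull$mat[, pairs$receptor[i]]),
    numeric(1))
  expect_lt(max(abs(rs)), 0.25)
  # at default noise, planted pairs outrank decoys by |r| in >= 90% of seeds
  wins <- 0
  for (s in 1:50) {
    sp <- generate_spatial(co, seed = 100 + s)
    rr <- vapply(seq_len(nrow(pairs)), function(i)
      abs(cor(sp$mat[, pairs$ligand[i]], sp$mat[, pairs$receptor[i]])),
      numeric(1))
    if (min(rr[pairs$active]) > max(rr[!pairs$active])) wins <- wins + 1
  }
  expect_gte(wins, 45)
})

test_that("accessibility truth is internally consistent", {
  co <- small_cohort(seed = 6)
  atac <- generate_atac(co, n_peaks = 500)
  pt <- atac$peak_truth
  rg <- co$truth$regulome
  # every target gene has a linked, motif-bearing, MES-shifted peak
  tp <- pt[pt$linked_gene %in% rg$target_genes, ]
  expect_true(all(tp$link & tp$motif_ap1 & tp$mes_shift))
  # linked peaks are within the default cis window of their gene
  ann <- co$annotation
  g <- ann[match(tp$linked_gene, ann$gene_id), ]
  gap <- pmax(0, pmax(g$start - tp$end, tp$start - g$end))
  expect_true(all(gap <= 250000))
  # MES-shifted peaks are more accessible in MES cells
  cells <- co$truth$cell
  mes <- cells$cell_id[cells$malignant & cells$phenotype == "MES"]
  pn <- cells$cell_id[cells$malignant & cells$phenotype == "PN"]
  shift_ratio <- mean(atac$peaks[pt$mes_shift, mes]) /
    mean(atac$peaks[pt$mes_shift, pn])
  expect_gt(shift_ratio, 1.5)
  # more planted links than peaks is a config error
  expect_error(generate_atac(co, n_peaks = 100), "candidate")
})
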