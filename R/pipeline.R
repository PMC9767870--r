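#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the complete flow — simulate, QC + normalize, CNV scan and
#' malignant/non-malignant split, cell-state classification, motif
#' deviations + cis-regulome inference, and the cohort statistics — and
#' writes all standard output files under `outdir`. Ground truth is used
#' only to evaluate recovery, never inside the analysis steps (the CNV
#' mixture components are oriented with the expression-cluster-free
#' larger-shift heuristic).
#'
#' @param outdir Output directory (created if needed).
#' @param config A [cohort_config()]; the default configuration defines
#'   the simulated study conditions.
#' @param seed Overrides the config seed when given.
#' @param n_peaks,link_effect Accessibility generator settings.
#' @param verbose Print progress messages.
#' @return List with the cohort, analysis objects and a `metrics` list of
#'   recovery/effect summaries.
#' @export
run_pipeline <- function(outdir = tempfile("gbmevolve"),
                         config = cohort_config(), seed = NULL,
                         n_peaks = 800, link_effect = 1, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  say("[1/5] simulate: generating cohort (seed %d)", config$seed)
  cohort <- generate_cohort(config)
  atac <- generate_atac(cohort, n_peaks = n_peaks,
                        link_effect = link_effect)
  seqs <- generate_sequences(atac$peak_truth, seed = config$seed + 3L)
  spatial <- generate_spatial(cohort)
  write_cohort(cohort, file.path(outdir, "cohort"))
  write_atac(atac, file.path(outdir, "atac"), seqs = seqs)

  say("[2/5] cnv: QC, normalization and arm-level mixture scan")
  counts <- qc_filter(cohort$counts, min_genes = 200)
  norm <- log_normalize(counts)
  scan <- cnv_scan(norm, cohort$annotation,
                   regions = cohort$config$arms$arm, seed = config$seed)
  write.csv(cnv_call_table(scan), file.path(outdir, "cnv_calls.csv"),
            row.names = FALSE)
  malignant <- scan$malignant

  say("[3/5] states: signature scoring and classification")
  sigs <- cohort$signatures
  mal_cells <- names(malignant)[malignant]
  norm_mal <- norm[, mal_cells, drop = FALSE]
  pn <- module_score(norm_mal, sigs$PN, seed = config$seed + 11L)
  mes <- module_score(norm_mal, sigs$MES, seed = config$seed + 12L)
  phenotype <- classify_pn_mes(pn, mes)
  cyc <- module_score(norm_mal, sigs$cycling, seed = config$seed + 13L)
  cycling <- classify_cycling(cyc)

  nonmal <- names(malignant)[!malignant]
  norm_non <- norm[, nonmal, drop = FALSE]
  lineage_sets <- sigs[c("microglia", "bmdm", "oligodendrocyte", "tcell")]
  lin_scores <- sapply(seq_along(lineage_sets), function(i)
    module_score(norm_non, lineage_sets[[i]], seed = config$seed + 20L + i))
  colnames(lin_scores) <- names(lineage_sets)
  lineage <- colnames(lin_scores)[max.col(lin_scores, ties.method = "first")]
  names(lineage) <- nonmal

  mono <- nonmal[lineage[nonmal] %in% c("microglia", "bmdm")]
  m_state <- if (length(mono) >= 10) {
    norm_mono <- norm[, mono, drop = FALSE]
    classify_m_state(
      module_score(norm_mono, sigs$M1, seed = config$seed + 31L),
      module_score(norm_mono, sigs$M2, seed = config$seed + 32L))
  } else NULL

  labels <- ifelse(malignant, paste0("malignant_", phenotype[names(malignant)]),
                   lineage[names(malignant)])
  labels[is.na(labels)] <- "unknown"
  names(labels) <- names(malignant)
  cell_labels <- data.frame(
    cell_id = names(malignant), malignant = as.logical(malignant),
    label = labels,
    cycling = ifelse(names(malignant) %in% names(cycling),
                     cycling[names(malignant)], NA),
    stringsAsFactors = FALSE)
  write.csv(cell_labels, file.path(outdir, "cell_labels.csv"),
            row.names = FALSE)
  comp <- composition_table(cohort$cell_meta[
    cohort$cell_meta$cell_id %in% names(labels), ], labels)
  write.csv(comp, file.path(outdir, "composition.csv"), row.names = FALSE)

  say("[4/5] regulome: deviations, links and intersection")
  ap1 <- pwm_from_consensus()
  motif_bearing <- names(which(scan_peaks(seqs, ap1)))
  bg <- background_peak_sets(atac$peaks, atac$intervals$gc,
                             seed = config$seed + 41L)
  membership <- list(AP1 = motif_bearing,
                     PN_like = atac$peak_truth$peak_id[
                       atac$peak_truth$motif_pn])
  dev <- compute_deviations(atac$peaks, membership, bg)
  write.csv(data.frame(motif = rownames(dev), dev, check.names = FALSE),
            file.path(outdir, "deviations.csv"), row.names = FALSE)

  atac_cells <- colnames(atac$peaks)
  mes_atac <- intersect(atac_cells, names(phenotype)[phenotype == "MES"])
  pn_atac <- intersect(atac_cells, names(phenotype)[phenotype == "PN"])
  de <- hurdle_de(norm, intersect(pn_atac, colnames(norm)),
                  intersect(mes_atac, colnames(norm)))
  de_up <- de$gene[de$q < 0.05 & de$logFC > 0]
  links <- link_enhancers(atac$peaks, norm, atac$intervals,
                          cohort$annotation, seed = config$seed + 42L)
  write.csv(links, file.path(outdir, "links.csv"), row.names = FALSE)
  da <- differential_accessibility(atac$peaks, pn_atac, mes_atac)
  reg <- infer_regulome(de_up, links, motif_bearing, da$specific)
  jsonlite::write_json(list(genes = reg$genes, support = reg$support),
                       file.path(outdir, "regulome.json"))

  say("[5/5] stats: paired cohort tests, survival, ligand-receptor")
  meta <- cohort$cell_meta
  mes_pct <- tapply(labels[meta$cell_id] == "malignant_MES" &
                      malignant[meta$cell_id],
                    meta$sample_id, function(z) 100 * mean(z))
  malig_frac <- tapply(malignant[meta$cell_id], meta$sample_id, mean)
  mes_of_malig <- 100 * mes_pct / pmax(100 * malig_frac, 1e-9)
  sm <- cohort$sample_meta
  prim <- sm$sample_id[sm$stage == "primary"]
  recu <- sm$sample_id[sm$stage == "recurrent"]
  ord <- match(sm$patient_id[match(prim, sm$sample_id)],
               sm$patient_id[match(recu, sm$sample_id)])
  pair_tab <- data.frame(patient_id = sm$patient_id[match(prim, sm$sample_id)],
                         value_primary = as.numeric(mes_of_malig[prim]),
                         value_recurrent = as.numeric(mes_of_malig[recu[ord]]))
  mes_shift <- paired_wilcoxon(pair_tab, alternative = "greater")

  tcell_pct <- tapply(labels[meta$cell_id] == "tcell", meta$sample_id,
                      function(z) 100 * mean(z))
  rec_pct <- tcell_pct[recu]
  groups <- split_tcell_groups(as.numeric(rec_pct))
  names(groups) <- recu
  hyper <- call_hypermutation(sm$tmb[match(recu, sm$sample_id)])
  tmb_test <- if (any(hyper) && any(!hyper)) {
    ranksum(as.numeric(rec_pct[hyper]), as.numeric(rec_pct[!hyper]),
            alternative = "greater")
  } else NULL

  surv_tab <- data.frame(
    sample_id = recu,
    time_days = sm$survival_days[match(recu, sm$sample_id)],
    event = sm$event[match(recu, sm$sample_id)],
    group = as.character(groups[recu]))
  km <- if (length(unique(surv_tab$group)) == 2)
    km_logrank(surv_tab) else NULL

  lr_sp <- lr_pair_correlation(spatial$mat, cohort$config$lr_pairs)
  lr_net <- lr_network_score(norm, labels, cohort$config$lr_pairs,
                             n_perm = 200, seed = config$seed + 51L)
  stats_out <- list(
    mes_shift = mes_shift[c("W", "p", "n_informative")],
    mes_pct_primary = mean(pair_tab$value_primary),
    mes_pct_recurrent = mean(pair_tab$value_recurrent),
    tcell_groups = table(groups),
    tmb_tcell_p = if (!is.null(tmb_test)) tmb_test$p else NA,
    logrank = if (!is.null(km)) km[c("chisq", "p", "n_events")] else NULL)
  jsonlite::write_json(stats_out, file.path(outdir, "stats.json"),
                       auto_unbox = TRUE, force = TRUE)
  write.csv(lr_sp, file.path(outdir, "lr_spatial.csv"), row.names = FALSE)
  write.csv(lr_net, file.path(outdir, "lr_network.csv"), row.names = FALSE)

  # recovery metrics vs planted truth (evaluation only)
  truth <- cohort$truth
  tc <- truth$cell[match(names(malignant), truth$cell$cell_id), ]
  metrics <- list(
    called_regions = scan$called,
    malignant_accuracy = mean(malignant == tc$malignant),
    pn_mes_accuracy = if (length(mal_cells)) {
      tm <- tc$phenotype[match(mal_cells, tc$cell_id)]
      mean(phenotype[mal_cells] == tm, na.rm = TRUE)
    } else NA,
    regulome_f1 = f1_score(reg$genes, truth$regulome$target_genes),
    mes_shift_p = mes_shift$p)
  write_json_file(list(metrics = metrics), file.path(outdir, "metrics.json"))
  list(cohort = cohort, atac = atac, spatial = spatial, scan = scan,
       phenotype = phenotype, cycling = cycling, lineage = lineage,
       m_state = m_state, labels = labels, dev = dev, de = de,
       links = links, regulome = reg, stats = stats_out,
       metrics = metrics, outdir = outdir)
}

f1_score <- function(called, truth) {
  tp <- length(intersect(called, truth))
  prec <- if (length(called)) tp / length(called) else 0
  rec <- if (length(truth)) tp / length(truth) else 0
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  invisible(path)
}
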