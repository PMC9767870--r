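#' Default chromosome-arm layout for the synthetic cohort
#'
#' Twenty arms (1p..10q) with 150 genes each, a scaled-down stand-in for the
#' protein-coding density of human chromosome arms.
#'
#' @param n_genes Genes per arm.
#' @return data.frame with columns `arm`, `chromosome`, `n_genes`.
#' @export
default_arms <- function(n_genes = 150) {
  chr <- rep(1:10, each = 2)
  arm <- paste0(chr, rep(c("p", "q"), 10))
  data.frame(arm = arm, chromosome = paste0("chr", chr),
             n_genes = n_genes, stringsAsFactors = FALSE)
}

#' Default ligand-receptor pair table
#'
#' Secreted-ligand/receptor pairs typical of the glioma microenvironment.
#' The `active`, `sender` and `receiver` columns define the planted
#' communication ground truth used by the generator.
#'
#' @return data.frame with columns `ligand`, `receptor`, `pathway`,
#'   `active`, `sender`, `receiver`.
#' @export
default_lr_pairs <- function() {
  data.frame(
    ligand   = c("IGF1", "PTN", "WNT3A", "OSM", "HGF", "LIF", "CNTF",
                 "NRG1", "NGF", "PDGFA"),
    receptor = c("IGF1R", "PTPRZ1", "LRP6", "OSMR", "MET", "LIFR", "CNTFR",
                 "ERBB4", "NTRK1", "PDGFRA"),
    pathway  = c("IGF", "PTN", "WNT", "OSM", "HGF", "LIF", "CNTF",
                 "NRG", "NGF", "PDGF"),
    active   = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6)),
    sender   = c("oligodendrocyte", "oligodendrocyte", "microglia", "bmdm",
                 rep(NA, 6)),
    receiver = c("malignant", "malignant", "malignant", "malignant",
                 rep(NA, 6)),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic paired cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: paired
#' primary/recurrent samples per patient, arm-scale CNVs carried by
#' malignant cells, a proneural-mesenchymal expression axis whose MES
#' fraction rises at recurrence, cycling subpopulations, microglia/BMDM with
#' M0/M1/M2 activation, T-cell subsets, a hypermutator tail in tumor
#' mutational burden coupled to T-cell infiltration, and survival linked to
#' T-cell fraction.
#'
#' @param n_patients Number of patients; each contributes one primary and
#'   one recurrent sample.
#' @param cells_per_sample Cells per sample.
#' @param arms Arm layout (see [default_arms()]).
#' @param cnv_events data.frame of planted CNVs: `arm`, `direction`
#'   (gain/loss), `fold` (expression dosage multiplier), `malignant_fraction`
#'   (carrier fraction among malignant cells), `stages` ("both", "primary" or
#'   "recurrent").
#' @param pn_mes PN/MES axis: program sizes, log-scale effect, MES fraction
#'   by stage.
#' @param cycling Cycling program size and fraction by stage and phenotype.
#' @param immune_mix Per-stage cell-type composition (must sum to 1).
#' @param m_state M1/M2 activation program sizes, effect, and per-stage
#'   M0/M1/M2 fractions among monocytic cells.
#' @param t_subsets T-cell subset fractions and marker effect.
#' @param lineage_effect Log-scale shift of lineage marker genes.
#' @param tmb_model Lognormal TMB parameters, hypermutator fraction among
#'   recurrences, hypermutator TMB range, and the T-cell fraction assigned
#'   to hypermutated samples.
#' @param survival_model Exponential survival: baseline hazard per day,
#'   log-hazard coefficient on T-cell fraction, censoring-time range (days).
#' @param regulome Candidate gene layout for cis-regulome recovery: total
#'   candidates, true AP1-target genes, MES-upregulated decoys, log effect.
#' @param lr_pairs Ligand-receptor table (see [default_lr_pairs()]).
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param gene_means Lognormal parameters of gene base means (arm genes are
#'   given a higher baseline so arm dosage is well measured).
#' @param patient_sdlog,cell_sdlog Lognormal sd of patient- and cell-level
#'   library-size factors (the patient factor induces within-pair
#'   correlation).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated config list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 12,
    cells_per_sample = 300,
    arms = default_arms(),
    cnv_events = data.frame(
      arm = c("7p", "10q"), direction = c("gain", "loss"),
      fold = c(1.3, 0.75), malignant_fraction = c(0.85, 0.85),
      stages = "both", stringsAsFactors = FALSE),
    pn_mes = list(n_genes = 50, effect = 1,
                  mes_frac = c(primary = 0.30, recurrent = 0.50)),
    cycling = list(n_genes = 50,
                   frac = c(primary.PN = 0.15, primary.MES = 0.05,
                            recurrent.PN = 0.15, recurrent.MES = 0.25)),
    immune_mix = list(
      primary = c(malignant = 0.55, oligodendrocyte = 0.23,
                  microglia = 0.145, bmdm = 0.07, tcell = 0.005),
      recurrent = c(malignant = 0.45, oligodendrocyte = 0.245,
                    microglia = 0.12, bmdm = 0.18, tcell = 0.005)),
    m_state = list(n_genes = 50, effect = 1,
                   fracs = list(primary = c(M0 = 0.7, M1 = 0.15, M2 = 0.15),
                                recurrent = c(M0 = 0.5, M1 = 0.25, M2 = 0.25))),
    t_subsets = list(effect = 1, program_genes = 30,
                     fracs = c(exhausted = 0.5, regulatory = 0.2,
                               proliferating = 0.15, NK = 0.15)),
    lineage_effect = 1.25,
    tmb_model = list(meanlog = log(2.5), sdlog = 0.5, hyper_frac = 0.16,
                     hyper_range = c(25, 60), tcell_frac_hyper = 0.03),
    survival_model = list(base_hazard = 1 / 500, log_hr_per_tcell = -40,
                          censor_range = c(200, 1500)),
    regulome = list(n_candidates = 300, n_targets = 30,
                    n_mes_up_decoys = 70, effect = 1),
    lr_pairs = default_lr_pairs(),
    nb_dispersion = 0.2,
    gene_means = list(arm_meanlog = log(4), arm_sdlog = 0.5,
                      other_meanlog = 0, other_sdlog = 0.5),
    patient_sdlog = 0.15,
    cell_sdlog = 0.3,
    seed = 1L) {
  cfg <- list(n_patients = n_patients, cells_per_sample = cells_per_sample,
              arms = arms, cnv_events = cnv_events, pn_mes = pn_mes,
              cycling = cycling, immune_mix = immune_mix, m_state = m_state,
              t_subsets = t_subsets, lineage_effect = lineage_effect,
              tmb_model = tmb_model, survival_model = survival_model,
              regulome = regulome, lr_pairs = lr_pairs,
              nb_dispersion = nb_dispersion, gene_means = gene_means,
              patient_sdlog = patient_sdlog, cell_sdlog = cell_sdlog,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  for (stage in c("primary", "recurrent")) {
    comp <- cfg$immune_mix[[stage]]
    if (abs(sum(comp) - 1) > 1e-8)
      stop_fmt("immune_mix composition for %s sums to %.4f, not 1",
               stage, sum(comp))
    if (any(comp < 0) || any(comp > 1))
      stop_fmt("immune_mix fractions must lie in [0, 1]")
    ms <- cfg$m_state$fracs[[stage]]
    if (abs(sum(ms) - 1) > 1e-8)
      stop_fmt("m_state fractions for %s must sum to 1", stage)
  }
  if (abs(sum(cfg$t_subsets$fracs) - 1) > 1e-8)
    stop_fmt("t_subsets fractions must sum to 1")
  if (any(cfg$cnv_events$fold <= 0)) stop_fmt("CNV folds must be positive")
  mf <- cfg$pn_mes$mes_frac
  if (any(mf < 0 | mf > 1)) stop_fmt("MES fractions must lie in [0, 1]")
  if (any(cfg$cycling$frac < 0 | cfg$cycling$frac > 1))
    stop_fmt("cycling fractions must lie in [0, 1]")
  bad <- setdiff(cfg$cnv_events$arm, cfg$arms$arm)
  if (length(bad)) stop_fmt("cnv_events reference unknown arms: %s",
                            paste(bad, collapse = ", "))
  cfg
}

# Gene universe with annotation and program membership.
build_gene_table <- function(cfg) {
  arms <- cfg$arms
  arm_genes <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    n <- arms$n_genes[i]
    # q arms are offset 120 Mb into the chromosome
    off <- if (grepl("q$", arms$arm[i])) 1.2e8 else 0
    data.frame(
      gene_id = sprintf("G%s.%03d", arms$arm[i], seq_len(n)),
      chromosome = arms$chromosome[i], arm = arms$arm[i],
      start = off + (seq_len(n) - 1) * 2e5,
      end = off + (seq_len(n) - 1) * 2e5 + 1e4,
      class = "arm", stringsAsFactors = FALSE)
  }))
  mk <- function(prefix, n, class, chrom = "chrP", arm = "Pq") {
    data.frame(gene_id = sprintf("%s.%03d", prefix, seq_len(n)),
               chromosome = chrom, arm = arm,
               start = 0, end = 1e4, class = class,
               stringsAsFactors = FALSE)
  }
  named <- function(ids, class, chrom = "chrP", arm = "Pq") {
    data.frame(gene_id = ids, chromosome = chrom, arm = arm, start = 0,
               end = 1e4, class = class, stringsAsFactors = FALSE)
  }
  tmark <- unique(unlist(default_t_markers()))
  lr_genes <- unique(c(cfg$lr_pairs$ligand, cfg$lr_pairs$receptor))
  other <- rbind(
    mk("PN", cfg$pn_mes$n_genes, "pn"),
    mk("MES", cfg$pn_mes$n_genes, "mes"),
    mk("CYC", cfg$cycling$n_genes, "cycling"),
    mk("MGL", 30, "microglia"), mk("BMD", 30, "bmdm"),
    mk("OLG", 30, "oligodendrocyte"), mk("TCL", 30, "tcell"),
    mk("M1P", cfg$m_state$n_genes, "m1"),
    mk("M2P", cfg$m_state$n_genes, "m2"),
    # subset-wide programs: real T subsets differ over many genes, not
    # just the handful of canonical markers used for labelling
    mk("TEX", cfg$t_subsets$program_genes %||% 30, "prog_exhausted"),
    mk("TRG", cfg$t_subsets$program_genes %||% 30, "prog_regulatory"),
    mk("TPR", cfg$t_subsets$program_genes %||% 30, "prog_proliferating"),
    mk("TNK", cfg$t_subsets$program_genes %||% 30, "prog_NK"),
    named(tmark, "tmarker"), named(lr_genes, "lr"),
    {
      n <- cfg$regulome$n_candidates
      data.frame(gene_id = sprintf("RG.%03d", seq_len(n)),
                 chromosome = "chrE", arm = "Eq",
                 start = (seq_len(n) - 1) * 1e6,
                 end = (seq_len(n) - 1) * 1e6 + 2e3,
                 class = "candidate", stringsAsFactors = FALSE)
    })
  # spread non-arm chrP genes over positions so the annotation is valid
  chrp <- other$chromosome == "chrP"
  other$start[chrp] <- (seq_len(sum(chrp)) - 1) * 2e5
  other$end[chrp] <- other$start[chrp] + 1e4
  rbind(arm_genes, other)
}

#' Generate a synthetic paired primary/recurrent cohort
#'
#' Draws a genes x cells count matrix from a negative-binomial model with
#' lognormal gene base means and patient/cell library-size factors. CNV
#' carrier cells have their arm gene means multiplied by the configured
#' dosage fold; phenotype, cycling, lineage and activation programs act as
#' additive log-scale shifts on their program genes. Returns the planted
#' ground truth alongside the data.
#'
#' @param config A [cohort_config()].
#' @return A list of class `gbm_cohort` with elements `counts` (integer
#'   genes x cells matrix), `cell_meta`, `sample_meta`, `annotation`,
#'   `signatures` and `truth` (per-cell and per-sample ground truth,
#'   including the CNV carrier matrix and regulome gene classes).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  genes <- build_gene_table(cfg)
  G <- nrow(genes)
  gidx <- function(cls) which(genes$class == cls)
  id_of <- function(cls) genes$gene_id[genes$class == cls]
  gm <- cfg$gene_means
  base_log <- ifelse(genes$class == "arm",
                     rnorm(G, gm$arm_meanlog, gm$arm_sdlog),
                     rnorm(G, gm$other_meanlog, gm$other_sdlog))
  # regulome candidate classes (fixed order: targets, decoys, neutral)
  rg_ids <- id_of("candidate")
  n_t <- cfg$regulome$n_targets
  n_d <- cfg$regulome$n_mes_up_decoys
  rg_class <- rep("neutral", length(rg_ids))
  rg_class[seq_len(n_t)] <- "target"
  rg_class[n_t + seq_len(n_d)] <- "mes_up_decoy"
  mes_up_rg <- rg_ids[rg_class != "neutral"]

  tmarkers <- default_t_markers()
  signatures <- list(
    PN = id_of("pn"), MES = id_of("mes"), cycling = id_of("cycling"),
    M1 = id_of("m1"), M2 = id_of("m2"),
    microglia = id_of("microglia"), bmdm = id_of("bmdm"),
    oligodendrocyte = id_of("oligodendrocyte"), tcell = id_of("tcell"),
    t_markers = tmarkers)

  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  patient_lib <- rnorm(cfg$n_patients, 0, cfg$patient_sdlog)
  names(patient_lib) <- patients

  samples <- expand.grid(patient_id = patients,
                         stage = c("primary", "recurrent"),
                         stringsAsFactors = FALSE)
  samples <- samples[order(samples$patient_id, samples$stage), ]
  samples$sample_id <- paste0(samples$patient_id, "-",
                              ifelse(samples$stage == "primary", "P", "R"))
  # hypermutator tail (recurrences only), coupled to T-cell infiltration
  tm <- cfg$tmb_model
  samples$hypermutated <- samples$stage == "recurrent" &
    rbinom(nrow(samples), 1, tm$hyper_frac) == 1
  samples$tmb <- rlnorm(nrow(samples), tm$meanlog, tm$sdlog)
  nh <- sum(samples$hypermutated)
  if (nh) samples$tmb[samples$hypermutated] <-
    runif(nh, tm$hyper_range[1], tm$hyper_range[2])
  samples$tcell_frac <- vapply(seq_len(nrow(samples)), function(i) {
    base <- cfg$immune_mix[[samples$stage[i]]][["tcell"]]
    if (samples$hypermutated[i]) tm$tcell_frac_hyper else base
  }, numeric(1))
  # survival per patient from recurrent-sample T-cell fraction
  sv <- cfg$survival_model
  rec <- samples[samples$stage == "recurrent", ]
  rate <- sv$base_hazard * exp(sv$log_hr_per_tcell * rec$tcell_frac)
  t_event <- rexp(nrow(rec), rate)
  t_cens <- runif(nrow(rec), sv$censor_range[1], sv$censor_range[2])
  surv <- data.frame(patient_id = rec$patient_id,
                     survival_days = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens))
  samples <- merge(samples, surv, by = "patient_id", sort = FALSE)
  samples <- samples[order(samples$patient_id, samples$stage), ]
  rownames(samples) <- NULL

  events <- cfg$cnv_events
  subsets <- names(cfg$t_subsets$fracs)
  size_nb <- 1 / cfg$nb_dispersion

  blocks <- vector("list", nrow(samples))
  cellrows <- vector("list", nrow(samples))
  carrier_rows <- vector("list", nrow(samples))
  for (si in seq_len(nrow(samples))) {
    stage <- samples$stage[si]
    pid <- samples$patient_id[si]
    n_c <- cfg$cells_per_sample
    comp <- cfg$immune_mix[[stage]]
    tf <- samples$tcell_frac[si]
    comp_adj <- comp
    comp_adj[["tcell"]] <- tf
    others <- setdiff(names(comp), "tcell")
    comp_adj[others] <- comp[others] * (1 - tf) / sum(comp[others])
    type_counts <- as.vector(rmultinom(1, n_c, comp_adj))
    cell_type <- rep(names(comp_adj), type_counts)

    cells <- data.frame(
      cell_id = sprintf("%s_%04d", samples$sample_id[si], seq_len(n_c)),
      sample_id = samples$sample_id[si], patient_id = pid, stage = stage,
      cell_type = cell_type, stringsAsFactors = FALSE)
    cells$malignant <- cells$cell_type == "malignant"
    cells$phenotype <- NA_character_
    nm <- sum(cells$malignant)
    if (nm) {
      mesfrac <- cfg$pn_mes$mes_frac[[stage]]
      cells$phenotype[cells$malignant] <-
        ifelse(rbinom(nm, 1, mesfrac) == 1, "MES", "PN")
    }
    cells$cycling <- FALSE
    for (ph in c("PN", "MES")) {
      idx <- which(cells$malignant & cells$phenotype == ph)
      if (length(idx)) {
        f <- cfg$cycling$frac[[paste(stage, ph, sep = ".")]]
        cells$cycling[idx] <- rbinom(length(idx), 1, f) == 1
      }
    }
    cells$m_state <- NA_character_
    mono <- which(cells$cell_type %in% c("microglia", "bmdm"))
    if (length(mono)) {
      fr <- cfg$m_state$fracs[[stage]]
      cells$m_state[mono] <- sample(names(fr), length(mono), replace = TRUE,
                                    prob = fr)
    }
    cells$t_subset <- NA_character_
    tc <- which(cells$cell_type == "tcell")
    if (length(tc))
      cells$t_subset[tc] <- sample(subsets, length(tc), replace = TRUE,
                                   prob = cfg$t_subsets$fracs)
    # CNV carriage among malignant cells, independent per event
    carr <- matrix(FALSE, n_c, nrow(events))
    colnames(carr) <- events$arm
    for (ei in seq_len(nrow(events))) {
      if (!(events$stages[ei] %in% c("both", stage))) next
      mi <- which(cells$malignant)
      if (length(mi))
        carr[mi, ei] <- rbinom(length(mi), 1,
                               events$malignant_fraction[ei]) == 1
    }

    # assemble log-means
    logmu <- matrix(base_log, G, n_c)
    logmu <- logmu + rep(rnorm(n_c, 0, cfg$cell_sdlog) + patient_lib[[pid]],
                         each = G)
    add <- function(gi, ci, delta) {
      if (length(gi) && length(ci))
        logmu[gi, ci] <<- logmu[gi, ci] + delta
    }
    for (ei in seq_len(nrow(events))) {
      ci <- which(carr[, ei])
      add(which(genes$arm == events$arm[ei]), ci, log(events$fold[ei]))
    }
    add(gidx("pn"), which(cells$phenotype %in% "PN"), cfg$pn_mes$effect)
    mes_cells <- which(cells$phenotype %in% "MES")
    add(gidx("mes"), mes_cells, cfg$pn_mes$effect)
    add(match(mes_up_rg, genes$gene_id), mes_cells, cfg$regulome$effect)
    add(gidx("cycling"), which(cells$cycling), cfg$pn_mes$effect)
    for (lin in c("microglia", "bmdm", "oligodendrocyte", "tcell"))
      add(gidx(lin), which(cells$cell_type == lin), cfg$lineage_effect)
    add(gidx("m1"), which(cells$m_state %in% "M1"), cfg$m_state$effect)
    add(gidx("m2"), which(cells$m_state %in% "M2"), cfg$m_state$effect)
    for (ss in subsets) {
      in_ss <- which(cells$t_subset %in% ss)
      add(match(tmarkers[[ss]], genes$gene_id), in_ss,
          cfg$t_subsets$effect)
      add(gidx(paste0("prog_", ss)), in_ss, cfg$t_subsets$effect)
    }
    lr <- cfg$lr_pairs
    for (pi in which(lr$active)) {
      add(match(lr$ligand[pi], genes$gene_id),
          which(cells$cell_type == lr$sender[pi]), 1.5)
      add(match(lr$receptor[pi], genes$gene_id),
          which(cells$cell_type == lr$receiver[pi]), 1.5)
    }

    cnt <- matrix(rnbinom(G * n_c, mu = exp(logmu), size = size_nb), G, n_c)
    colnames(cnt) <- cells$cell_id
    blocks[[si]] <- cnt
    cellrows[[si]] <- cells
    carrier_rows[[si]] <- carr
  }

  counts <- do.call(cbind, blocks)
  rownames(counts) <- genes$gene_id
  storage.mode(counts) <- "integer"
  cell_truth <- do.call(rbind, cellrows)
  carriers <- do.call(rbind, carrier_rows)
  rownames(carriers) <- cell_truth$cell_id

  annotation <- genes[, c("chromosome", "start", "end", "gene_id", "arm")]
  sample_meta <- samples[, c("sample_id", "patient_id", "stage", "tmb",
                             "survival_days", "event")]
  cell_meta <- cell_truth[, c("cell_id", "sample_id", "patient_id", "stage")]

  out <- list(
    counts = counts,
    cell_meta = cell_meta,
    sample_meta = sample_meta,
    annotation = annotation,
    signatures = signatures,
    truth = list(
      cell = cell_truth,
      carriers = carriers,
      sample = samples,
      cnv_events = events,
      regulome = list(candidate_genes = rg_ids, class = rg_class,
                      target_genes = rg_ids[rg_class == "target"],
                      mes_up_genes = mes_up_rg),
      lr_active = cfg$lr_pairs[cfg$lr_pairs$active, , drop = FALSE]),
    config = cfg)
  class(out) <- "gbm_cohort"
  out
}

#' @export
print.gbm_cohort <- function(x, ...) {
  cat(sprintf("gbm_cohort: %d genes x %d cells, %d samples (%d patients)\n",
              nrow(x$counts), ncol(x$counts), nrow(x$sample_meta),
              length(unique(x$sample_meta$patient_id))))
  invisible(x)
}

#' Write a synthetic cohort to standard on-disk formats
#'
#' Emits MatrixMarket counts + gene/barcode lists, CSV cell and sample
#' metadata, a BED-like gene annotation, signature JSON and a
#' `truth.json` ground-truth file.
#'
#' @param cohort A `gbm_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the output directory.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_matrix(cohort$counts, dir)
  write.csv(cohort$cell_meta, file.path(dir, "cell_meta.csv"),
            row.names = FALSE)
  write.csv(cohort$sample_meta, file.path(dir, "sample_meta.csv"),
            row.names = FALSE)
  write_gene_annotation(cohort$annotation, file.path(dir, "genes.bed.tsv"))
  write_signatures(cohort$signatures[names(cohort$signatures) != "t_markers"],
                   file.path(dir, "signatures.json"))
  truth <- cohort$truth
  truth$carriers <- NULL # large logical matrix; per-cell table retains flags
  jsonlite::write_json(truth, file.path(dir, "truth.json"), dataframe = "rows")
  invisible(dir)
}
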