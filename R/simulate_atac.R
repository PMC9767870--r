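#' Generate synthetic accessibility data matched to a cohort
#'
#' Builds a peaks x cells Poisson count matrix over the cohort's malignant
#' cells. Each regulome candidate gene receives one proximal peak (within
#' the cis window); peaks tied to true AP1-target genes carry the AP1 motif
#' and have their accessibility mean raised by `link_effect` (log scale) in
#' MES cells, so that peak and gene activity co-vary. Decoy peaks break
#' exactly one of the three regulome criteria. Filler peaks include
#' MES-specific and PN-specific sets used by the motif-deviation analyses.
#'
#' @param cohort A `gbm_cohort` from [generate_cohort()].
#' @param n_peaks Total number of peaks (>= number of candidate genes).
#' @param link_effect Log-scale accessibility shift of state-coupled peaks.
#' @param ap1_filler_frac Probability that a MES-specific filler peak
#'   carries an AP1 motif; flat fillers and neutral candidates carry one
#'   with probability `ap1_background_frac`.
#' @param ap1_background_frac Background AP1 motif rate.
#' @param peak_meanlog,peak_sdlog Lognormal parameters of peak base rates.
#' @param depth_sdlog Lognormal sd of per-cell depth factors.
#' @param seed Seed (defaults to the cohort seed + 1).
#' @return List of class `gbm_atac` with `peaks` (integer peaks x cells),
#'   `intervals` (peak_id, chromosome, start, end, gc), and `peak_truth`
#'   (motif membership, state coupling, linked gene).
#' @export
generate_atac <- function(cohort, n_peaks = 800, link_effect = 1,
                          ap1_filler_frac = 0.6, ap1_background_frac = 0.3,
                          peak_meanlog = 0, peak_sdlog = 0.5,
                          depth_sdlog = 0.3, seed = NULL) {
  stopifnot(inherits(cohort, "gbm_cohort"))
  seed <- seed %||% (cohort$config$seed + 1L)
  with_seed(seed, {
    rg <- cohort$truth$regulome
    n_cand <- length(rg$candidate_genes)
    if (n_cand > n_peaks)
      stop_fmt("more candidate links (%d) than peaks (%d)", n_cand, n_peaks)
    annot <- cohort$annotation
    cand <- annot[match(rg$candidate_genes, annot$gene_id), ]

    # proximal peak 30 kb downstream of each candidate gene
    prox <- data.frame(
      peak_id = sprintf("PKp.%03d", seq_len(n_cand)),
      chromosome = cand$chromosome,
      start = cand$start + 3e4, end = cand$start + 3e4 + 500,
      linked_gene = cand$gene_id, stringsAsFactors = FALSE)
    cls <- rg$class
    half <- seq_along(cls) %% 2 == 0
    prox$link <- cls == "target" | (cls == "mes_up_decoy" & !half)
    prox$mes_shift <- prox$link
    prox$motif_ap1 <- cls == "target" |
      (cls == "mes_up_decoy" & half) |
      (cls == "neutral" & rbinom(n_cand, 1, ap1_background_frac) == 1)
    prox$pn_shift <- FALSE

    n_fill <- n_peaks - n_cand
    fill <- data.frame(
      peak_id = sprintf("PKf.%03d", seq_len(n_fill)),
      chromosome = "chrF", start = (seq_len(n_fill) - 1) * 1e6,
      end = (seq_len(n_fill) - 1) * 1e6 + 500,
      linked_gene = NA_character_, link = FALSE, stringsAsFactors = FALSE)
    third <- pmin(n_fill %/% 5, 100)
    fill$mes_shift <- seq_len(n_fill) <= third
    fill$pn_shift <- seq_len(n_fill) > third & seq_len(n_fill) <= 2 * third
    fill$motif_ap1 <- rbinom(n_fill, 1, ifelse(fill$mes_shift,
                                               ap1_filler_frac,
                                               ap1_background_frac)) == 1

    peaks_df <- rbind(prox, fill)
    peaks_df$gc <- runif(nrow(peaks_df), 0.35, 0.65)
    # a PN-motif set for deviation/cluster analyses, defined by membership
    peaks_df$motif_pn <- peaks_df$pn_shift |
      (!peaks_df$mes_shift & rbinom(nrow(peaks_df), 1, 0.1) == 1)

    cells <- cohort$truth$cell
    mal <- cells[cells$malignant, ]
    n_cells <- nrow(mal)
    base <- rlnorm(nrow(peaks_df), peak_meanlog, peak_sdlog)
    depth <- rlnorm(n_cells, 0, depth_sdlog)
    logl <- outer(log(base), log(depth), "+")
    is_mes <- mal$phenotype == "MES"
    logl[peaks_df$mes_shift, is_mes] <-
      logl[peaks_df$mes_shift, is_mes] + link_effect
    logl[peaks_df$pn_shift, !is_mes] <-
      logl[peaks_df$pn_shift, !is_mes] + link_effect
    pk <- matrix(rpois(length(logl), exp(logl)), nrow(peaks_df), n_cells)
    dimnames(pk) <- list(peaks_df$peak_id, mal$cell_id)
    storage.mode(pk) <- "integer"

    out <- list(
      peaks = pk,
      intervals = peaks_df[, c("peak_id", "chromosome", "start", "end",
                               "gc")],
      peak_truth = peaks_df)
    class(out) <- "gbm_atac"
    out
  })
}

#' Generate peak sequences with embedded motif consensus
#'
#' Uniform-random ACGT sequences per peak; peaks flagged as motif-bearing
#' receive at least one embedded consensus (on either strand) at a recorded
#' offset, and non-bearing peaks are resampled until the exact consensus is
#' absent from both strands.
#'
#' @param peak_truth data.frame with `peak_id` and `motif_ap1` columns
#'   (as produced by [generate_atac()]).
#' @param peak_length Sequence length in bp (>= motif length).
#' @param motif_consensus Consensus string to embed (default the AP1
#'   TPA-response element TGACTCA).
#' @param seed Seed.
#' @return Named character vector of sequences; the embedding offsets
#'   (0-based, forward strand) and strands are in attribute `"embedding"`.
#' @export
generate_sequences <- function(peak_truth, peak_length = 200,
                               motif_consensus = "TGACTCA", seed = 1L) {
  w <- nchar(motif_consensus)
  if (peak_length < w) stop_fmt("peak_length shorter than motif")
  rc <- revcomp_string(motif_consensus)
  with_seed(seed, {
    n <- nrow(peak_truth)
    seqs <- character(n)
    offs <- rep(NA_integer_, n)
    strands <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      repeat {
        s <- paste(sample(c("A", "C", "G", "T"), peak_length,
                          replace = TRUE), collapse = "")
        has <- grepl(motif_consensus, s, fixed = TRUE) ||
          grepl(rc, s, fixed = TRUE)
        if (!peak_truth$motif_ap1[i] && !has) break
        if (peak_truth$motif_ap1[i]) {
          off <- sample.int(peak_length - w + 1, 1) - 1L
          strand <- sample(c("+", "-"), 1)
          ins <- if (strand == "+") motif_consensus else rc
          s <- paste0(substr(s, 1, off), ins,
                      substr(s, off + w + 1, peak_length))
          offs[i] <- off
          strands[i] <- strand
          break
        }
      }
      seqs[i] <- s
    }
    names(seqs) <- peak_truth$peak_id
    attr(seqs, "embedding") <- data.frame(peak_id = peak_truth$peak_id,
                                          offset = offs, strand = strands,
                                          stringsAsFactors = FALSE)
    seqs
  })
}

revcomp_string <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

#' Write peak sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output FASTA path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Generate spatial ROI pseudobulk with ligand-receptor gradients
#'
#' Each region of interest (ROI) carries a tumor-to-margin gradient value
#' in \[0, 1\]; for active ligand-receptor pairs, the log-means of ligand
#' and receptor both rise with the gradient, so the pair co-varies across
#' ROIs. Inactive pairs have flat means.
#'
#' @param cohort A `gbm_cohort` (supplies the LR pair table).
#' @param n_rois Number of ROIs.
#' @param gradient_effect Log-scale slope of active genes on the gradient.
#' @param noise_sd Lognormal noise sd (0 gives the deterministic limit).
#' @param seed Seed (defaults to the cohort seed + 2).
#' @return List with `mat` (ROIs x genes), `roi_meta` (roi_id, gradient)
#'   and `lr_truth` (the active pair table).
#' @export
generate_spatial <- function(cohort, n_rois = 24, gradient_effect = 1.5,
                             noise_sd = 0.25, seed = NULL) {
  stopifnot(inherits(cohort, "gbm_cohort"))
  seed <- seed %||% (cohort$config$seed + 2L)
  lr <- cohort$config$lr_pairs
  genes <- unique(c(lr$ligand, lr$receptor))
  with_seed(seed, {
    g <- runif(n_rois)
    logmu <- matrix(0, n_rois, length(genes),
                    dimnames = list(sprintf("ROI%02d", seq_len(n_rois)),
                                    genes))
    for (i in which(lr$active)) {
      logmu[, lr$ligand[i]] <- logmu[, lr$ligand[i]] + gradient_effect * g
      logmu[, lr$receptor[i]] <- logmu[, lr$receptor[i]] +
        gradient_effect * g
    }
    mat <- exp(logmu + matrix(rnorm(length(logmu), 0, noise_sd),
                              n_rois, length(genes)))
    list(mat = mat,
         roi_meta = data.frame(roi_id = rownames(mat), gradient = g,
                               stringsAsFactors = FALSE),
         lr_truth = lr[lr$active, , drop = FALSE])
  })
}

#' Write accessibility data to standard formats
#'
#' MatrixMarket peak counts plus peak/barcode lists, a BED file of peak
#' intervals (0-based half-open) and a FASTA of peak sequences.
#'
#' @param atac A `gbm_atac`.
#' @param dir Output directory.
#' @param seqs Optional named sequences from [generate_sequences()].
#' @return Invisibly, the directory.
#' @export
write_atac <- function(atac, dir, seqs = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_matrix(atac$peaks, dir, prefix = "peaks_")
  iv <- atac$intervals
  write.table(data.frame(iv$chromosome, iv$start, iv$end, iv$peak_id),
              file.path(dir, "peaks.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(seqs)) write_fasta(seqs, file.path(dir, "peaks.fasta"))
  invisible(dir)
}
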