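#' Read a genes x cells count matrix from MatrixMarket files
#'
#' Reads a sparse count matrix in MatrixMarket coordinate format together
#' with its row (gene) and column (barcode) annotation files, one identifier
#' per line (tab-separated files are accepted; the first field is used).
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param genes_path Path to the gene identifier file (rows).
#' @param barcodes_path Path to the cell barcode file (columns).
#' @return A `dgCMatrix` of non-negative integer counts with gene and cell
#'   identifiers as dimnames.
#' @export
read_count_matrix <- function(matrix_path, genes_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- read_id_column(genes_path)
  cells <- read_id_column(barcodes_path)
  if (nrow(m) != length(genes))
    stop_fmt("matrix has %d rows but %d gene identifiers", nrow(m),
             length(genes))
  if (ncol(m) != length(cells))
    stop_fmt("matrix has %d columns but %d barcodes", ncol(m), length(cells))
  if (anyDuplicated(genes)) stop_fmt("gene identifiers are not unique")
  if (anyDuplicated(cells)) stop_fmt("cell barcodes are not unique")
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  if (length(m@x) && any(m@x < 0))
    stop_fmt("count matrix contains negative entries")
  if (length(m@x) && any(m@x %% 1 != 0))
    stop_fmt("count matrix contains non-integer entries")
  dimnames(m) <- list(genes, cells)
  m
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write a count matrix as MatrixMarket + annotation files
#'
#' Inverse of [read_count_matrix()]; the round trip is bit-identical for
#' integer matrices.
#'
#' @param counts Genes x cells matrix with dimnames.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_count_matrix <- function(counts, dir, prefix = "") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("matrix.mtx", "genes.tsv",
                                           "barcodes.tsv")))
  Matrix::writeMM(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
                  paths[1])
  writeLines(rownames(counts), paths[2])
  writeLines(colnames(counts), paths[3])
  invisible(paths)
}

#' Quality-control filter for cells
#'
#' Removes cells with a mitochondrial count fraction above `max_mito_frac`
#' or with fewer than `min_genes` genes detected (count > 0). Genes are
#' never removed.
#'
#' @param counts Genes x cells count matrix.
#' @param mito_gene_ids Character vector of mitochondrial gene identifiers
#'   (must be a subset of the matrix genes; may be empty). Mitochondrial
#'   genes are supplied explicitly rather than matched by name prefix so the
#'   rule stays species- and annotation-agnostic.
#' @param max_mito_frac Maximum tolerated mitochondrial fraction of total
#'   counts per cell (default 0.025).
#' @param min_genes Minimum number of detected genes per cell (default 200).
#' @return The filtered count matrix.
#' @export
qc_filter <- function(counts, mito_gene_ids = character(),
                      max_mito_frac = 0.025, min_genes = 200) {
  missing <- setdiff(mito_gene_ids, rownames(counts))
  if (length(missing))
    stop_fmt("mitochondrial genes absent from matrix: %s",
             paste(head(missing, 5), collapse = ", "))
  totals <- col_sums(counts)
  mito <- if (length(mito_gene_ids)) {
    col_sums(counts[mito_gene_ids, , drop = FALSE])
  } else rep(0, ncol(counts))
  mito_frac <- ifelse(totals > 0, mito / totals, 0)
  n_genes <- col_sums(counts > 0)
  keep <- mito_frac <= max_mito_frac & n_genes >= min_genes
  if (!any(keep)) stop_fmt("empty after QC: all %d cells removed",
                           ncol(counts))
  n_rm <- sum(!keep)
  if (n_rm > 0)
    message(sprintf("qc_filter: removed %d of %d cells (%d high-mito, %d low-complexity)",
                    n_rm, ncol(counts), sum(mito_frac > max_mito_frac),
                    sum(n_genes < min_genes)))
  counts[, keep, drop = FALSE]
}

#' Log-normalize a count matrix
#'
#' Per-cell total-count scaling to `scale` followed by a natural-log
#' `log1p` transform: `y[g,c] = ln(1 + scale * count[g,c] / total[c])`.
#'
#' @param counts Genes x cells count matrix.
#' @param scale Scale factor (default 10,000).
#' @return Normalized matrix of the same class and dimensions.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  totals <- col_sums(counts)
  zero <- which(totals == 0)
  if (length(zero))
    stop_fmt("cell(s) with zero total counts: %s",
             paste(head(colnames(counts)[zero] %||% zero, 5), collapse = ", "))
  if (is(counts, "dgCMatrix")) {
    out <- counts
    out@x <- log1p(out@x * scale / rep.int(totals, diff(out@p)))
    out
  } else {
    log1p(sweep(as.matrix(counts), 2, totals, "/") * scale)
  }
}

#' Select highly variable genes
#'
#' Mean/dispersion selection: genes are placed into `n_bins` equal-occupancy
#' bins of mean expression, the log dispersion (variance over mean) is
#' z-scored within each bin, and genes with mean in `[mean_lo, mean_hi]` and
#' dispersion z-score at least `disp_z_min` are returned, ordered by
#' decreasing z-score.
#'
#' @param norm Genes x cells normalized matrix.
#' @param mean_lo,mean_hi Mean-expression window (defaults 0.1 and 8).
#' @param disp_z_min Minimum within-bin dispersion z-score (default 1).
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of gene identifiers, most variable first.
#' @export
select_hvg <- function(norm, mean_lo = 0.1, mean_hi = 8, disp_z_min = 1,
                       n_bins = 20) {
  if (ncol(norm) < 2) stop_fmt("select_hvg requires at least 2 cells")
  mu <- row_means(norm)
  v <- row_vars(norm)
  disp <- ifelse(mu > 0, v / mu, 0)
  log_disp <- log(pmax(disp, 1e-12))
  if (nrow(norm) < n_bins) {
    warn_fmt("fewer than %d genes; using a single dispersion bin", n_bins)
    n_bins <- 1L
  }
  bins <- rank_bins(mu, n_bins)
  z <- numeric(length(mu))
  for (b in unique(bins)) {
    idx <- which(bins == b)
    s <- sd(log_disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else
      (log_disp[idx] - mean(log_disp[idx])) / s
  }
  keep <- which(mu >= mean_lo & mu <= mean_hi & z >= disp_z_min)
  genes <- rownames(norm)[keep]
  genes[order(z[keep], decreasing = TRUE)]
}

#' Read per-cell metadata
#'
#' CSV with columns `cell_id`, `sample_id`, `patient_id`, `stage`.
#'
#' @param path CSV path.
#' @return A data.frame, validated.
#' @export
read_cell_meta <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "sample_id", "patient_id", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fmt("cell metadata missing columns: %s",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id)) stop_fmt("duplicate cell_id in metadata")
  df
}

#' Read per-sample metadata
#'
#' CSV with columns `sample_id`, `patient_id`, `stage` and optionally
#' `tmb` (mutations per megabase), `survival_days`, `event`.
#'
#' @param path CSV path.
#' @return A data.frame, validated.
#' @export
read_sample_meta <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fmt("sample metadata missing columns: %s",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_fmt("duplicate sample_id")
  if (!is.null(df$tmb) && any(df$tmb < 0)) stop_fmt("negative TMB")
  df
}

#' Read a gene annotation table with chromosome-arm coordinates
#'
#' Tab-separated BED-like file (0-based half-open) with columns
#' `chromosome`, `start`, `end`, `gene_id`, `arm`.
#'
#' @param path File path.
#' @return A data.frame with those columns.
#' @export
read_gene_annotation <- function(path) {
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chromosome", "start", "end", "gene_id", "arm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fmt("annotation missing columns: %s",
                             paste(miss, collapse = ", "))
  validate_annotation(df)
  df
}

validate_annotation <- function(df) {
  if (any(df$start >= df$end)) stop_fmt("annotation has start >= end")
  if (anyDuplicated(df$gene_id)) stop_fmt("duplicate gene_id in annotation")
  bad <- !mapply(function(chr, arm) grepl(sub("^chr", "", chr), arm,
                                          fixed = TRUE),
                 df$chromosome, df$arm)
  if (any(bad)) stop_fmt("arm not consistent with chromosome for %d genes",
                         sum(bad))
  invisible(df)
}

#' Write a gene annotation table
#' @param annot Annotation data.frame (see [read_gene_annotation()]).
#' @param path Output path.
#' @export
write_gene_annotation <- function(annot, path) {
  write.table(annot[, c("chromosome", "start", "end", "gene_id", "arm")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read gene signatures
#'
#' Either a JSON object mapping signature names to gene lists, or a plain
#' newline-delimited gene list (one signature named after the file).
#'
#' @param path File path (`.json` or plain text).
#' @return Named list of character vectors.
#' @export
read_signatures <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    sigs <- jsonlite::read_json(path, simplifyVector = TRUE)
    lapply(sigs, as.character)
  } else {
    genes <- readLines(path)
    out <- list(genes[nzchar(genes)])
    names(out) <- sub("\\.[^.]*$", "", basename(path))
    out
  }
}

#' @importFrom utils write.table
NULL
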