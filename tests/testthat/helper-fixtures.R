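# Shared in-code fixtures for unit tests.

# A small but structured cohort for fast state/recovery checks.
small_cohort <- function(seed = 1, n_patients = 2, cells = 150, ...) {
  generate_cohort(cohort_config(n_patients = n_patients,
                                cells_per_sample = cells, seed = seed, ...))
}

# Tiny deterministic count matrix with dimnames.
toy_counts <- function(values, n_genes, n_cells,
                       genes = sprintf("g%d", seq_len(n_genes)),
                       cells = sprintf("c%d", seq_len(n_cells))) {
  m <- matrix(as.integer(values), n_genes, n_cells,
              dimnames = list(genes, cells))
  m
}

# Normalized-scale toy matrix (continuous values).
toy_norm <- function(values, n_genes, n_cells,
                     genes = sprintf("g%d", seq_len(n_genes)),
                     cells = sprintf("c%d", seq_len(n_cells))) {
  matrix(values, n_genes, n_cells, dimnames = list(genes, cells))
}

expect_silent_messages <- function(expr) suppressMessages(expr)
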