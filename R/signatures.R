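#' Canonical monocytic activation signatures
#'
#' Marker gene lists for the classically activated, pro-inflammatory (M1)
#' and alternatively activated, inflammation-resolving (M2) programs of
#' monocytic-lineage cells (microglia and bone-marrow-derived monocytes),
#' aggregated from the innate-immunity literature. Shared genes (e.g.
#' antigen-presentation machinery) appear in both lists. The same lists are
#' shipped as a JSON fixture under `extdata/signatures/m1_m2.json`.
#'
#' @return Named list with elements `M1` and `M2`.
#' @export
monocyte_activation_signatures <- function() {
  list(
    M1 = c("CCL2", "CCL3", "CCL4", "CCL5", "CCL8", "CCR7", "CD74", "CSF2",
           "CXCL10", "HLA-DRA", "HLA-DRB", "IFNG", "IL1B", "IL1R1", "IL6",
           "INOS", "IRF5", "NFKB1", "TLR2", "TLR4", "TNF"),
    M2 = c("ARG1", "CD74", "CCL1", "CCL17", "CCL22", "CXCL16", "CXCR4",
           "HLA-DRA", "HLA-DRB", "IL10", "IL4", "IRF4", "MRC1", "NFKB1",
           "TGFB1", "TNF")
  )
}

#' Default T-cell subset marker map
#'
#' Marker sets used to assign T-cell clusters to exhausted (immune
#' checkpoints), regulatory, proliferating and natural-killer phenotypes.
#'
#' @return Named list of character vectors.
#' @export
default_t_markers <- function() {
  list(
    exhausted = c("PDCD1", "CTLA4", "LAG3", "HAVCR2", "TIGIT"),
    regulatory = c("FOXP3", "IL2RA", "IKZF2"),
    proliferating = c("MKI67", "TOP2A"),
    NK = c("NKG7", "GNLY", "KLRD1", "PRF1")
  )
}

#' Write signatures to JSON
#' @param sigs Named list of character vectors.
#' @param path Output path.
#' @export
write_signatures <- function(sigs, path) {
  jsonlite::write_json(sigs, path, pretty = TRUE)
  invisible(path)
}
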