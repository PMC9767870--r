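{
  "M1": ["CCL2", "CCL3", "CCL4", "CCL5", "CCL8", "CCR7", "CD74", "CSF2",
         "CXCL10", "HLA-DRA", "HLA-DRB", "IFNG", "IL1B", "IL1R1", "IL6",
         "INOS", "IRF5", "NFKB1", "TLR2", "TLR4", "TNF"],
  "M2": ["ARG1", "CD74", "CCL1", "CCL17", "CCL22", "CXCL16", "CXCR4",
         "HLA-DRA", "HLA-DRB", "IL10", "IL4", "IRF4", "MRC1", "NFKB1",
         "TGFB1", "TNF"]
}
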