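# non-exported package infrastructure

# let data.table find its [] methods when this package is loaded via
# devtools or as an import-only dependency
.datatable.aware <- TRUE

utils::globalVariables(c(".N", "gene_a", "gene_b"))
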