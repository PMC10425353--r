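# small shared fixtures built in code

smallExperiment <- function(seed = 1, n_pairs = 6, nuclei = 80,
                            n_genes = 60, ...) {
    cfg <- simulationConfig(seed = seed, n_pairs = n_pairs,
                            nuclei_per_subject = nuclei,
                            n_genes = n_genes, ...)
    sub <- simulateSubjects(cfg)
    be <- simulateCounts(sub, cfg)
    list(cfg = cfg, subjects = sub, be = be,
         meta = as.data.frame(SummarizedExperiment::colData(be)),
         panel = S4Vectors::metadata(be)$panel)
}

toyCounts <- function() {
    m <- matrix(c(2, 0, 1, 0, 5,
                  0, 0, 0, 0, 0,
                  1, 1, 1, 1, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("gA", "gB", "gC"),
                                paste0("n", 1:5)))
    Matrix::Matrix(m, sparse = TRUE)
}
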