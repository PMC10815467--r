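# Shared in-code fixtures. The packaged bundle is deterministic, so building
# it once per test run is safe and cheap.

the_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fixture_small()
    cache
  }
})

make_counts <- function(mat, genes = NULL, barcodes = NULL) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(mat)))
  if (is.null(barcodes)) barcodes <- sprintf("c%02d", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, barcodes)
  methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
}

# Minimal priors for the published 4-gene example chain.
areg_chain_priors <- function() {
  prior_knowledge(
    data.frame(ligand = "AREG", receptor = "ERBB3"),
    data.frame(receptor = "ERBB3", tf = "FOXA1"),
    data.frame(tf = "FOXA1", target = "ESR1")
  )
}

fixture_pipeline_config <- function(bundle, seed, ...) {
  pipeline_config(bundle = bundle, seed = seed, min_genes = 50, ...)
}
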