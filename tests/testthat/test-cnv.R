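make_positions <- function(genes, chroms) {
  tibble::tibble(gene = genes, chrom = factor(chroms, unique(chroms)),
                 start = ave(seq_along(genes), chroms, FUN = seq_along) * 100,
                 end = ave(seq_along(genes), chroms, FUN = seq_along) * 100 + 50)
}

test_that("cells identical to the reference leave zero residuals", {
  counts <- matrix(rep(c(3, 1, 4, 1, 5, 9), 6), nrow = 6)
  cm <- make_counts(counts)
  pos <- make_positions(rownames(cm), rep(c("chr1", "chr2"), each = 3))
  prof <- build_cnv_profile(cm, pos, reference_cells = colnames(cm)[1:3],
                            window = 3)
  expect_true(all(abs(prof$residuals) < 1e-12))
  sc <- cnv_score(prof)
  expect_true(all(sc$score == 0))
})

test_that("the full residual pipeline matches a loop-based oracle", {
  set.seed(91)
  for (window in c(1, 3, 7)) {
    n_genes <- 18; n_cells <- 12
    counts <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells)
    cm <- make_counts(counts)
    chroms <- rep(c("chr1", "chr2", "chr3"), each = 6)
    pos <- make_positions(rownames(cm), chroms)
    ref <- colnames(cm)[1:4]
    prof <- build_cnv_profile(cm, pos, ref, window = window, cutoff = 0)
    # oracle works on the same gene order the profile reports
    ord <- match(colnames(prof$residuals), rownames(cm))
    oracle <- oracle_cnv_residuals(counts[ord, , drop = FALSE],
                                   chroms[ord], ref_idx = 1:4,
                                   window = window)
    expect_lt(max(abs(prof$residuals - oracle)), 1e-12)
    # reference mean residual profile is exactly zero
    expect_lt(max(abs(colMeans(prof$residuals[ref, ]))), 1e-12)
  }
})

test_that("window = 1 smoothing is the identity", {
  set.seed(12)
  counts <- matrix(rpois(10 * 8, 4), 10, 8)
  cm <- make_counts(counts)
  pos <- make_positions(rownames(cm), rep("chr1", 10))
  p1 <- build_cnv_profile(cm, pos, colnames(cm)[1:3], window = 1, cutoff = 0)
  oracle <- oracle_cnv_residuals(counts[match(colnames(p1$residuals),
                                              rownames(cm)), ],
                                 rep("chr1", ncol(p1$residuals)), 1:3, 1)
  expect_lt(max(abs(p1$residuals - oracle)), 1e-12)
  expect_error(build_cnv_profile(cm, pos, colnames(cm)[1:3], window = 2),
               "odd")
})

test_that("cumulative scores sum squared residuals, order-free", {
  prof <- structure(list(
    residuals = matrix(c(0.1, 0, -0.2, 0), 2, 2, byrow = FALSE,
                       dimnames = list(c("a", "b"), c("g1", "g2")))),
    class = "cnv_profile")
  sc <- cnv_score(prof)
  expect_equal(sc$score[sc$cell == "a"], 0.1^2 + 0.2^2)
  expect_equal(sc$score[sc$cell == "b"], 0)
  prof2 <- prof
  prof2$residuals <- prof$residuals[, c("g2", "g1")]
  expect_equal(cnv_score(prof2)$score, sc$score)
  expect_equal(cnv_score(prof, "absolute")$score[1], 0.3)
})

test_that("malignancy calls separate planted gains from the reference", {
  b <- the_fixture()
  prof <- build_cnv_profile(b$counts, b$positions, b$truth$reference_cells)
  sc <- cnv_score(prof)
  calls <- call_malignant(sc, b$cells, b$truth$reference_cells)
  expect_identical(calls$subcluster[calls$is_malignant], "m1")
  expect_false(calls$is_malignant[calls$subcluster == "m2"])

  none <- call_malignant(sc, b$cells, b$truth$reference_cells, alpha = 0)
  expect_false(any(none$is_malignant))

  # identical distribution -> not malignant: score the reference against itself
  half <- b$truth$reference_cells[1:50]
  other <- setdiff(b$truth$reference_cells, half)
  cells2 <- b$cells
  cells2$subcluster[cells2$barcode %in% half] <- "ref_as_obs"
  calls2 <- call_malignant(sc, cells2[cells2$barcode %in% c(half), ], other)
  expect_false(calls2$is_malignant[calls2$subcluster == "ref_as_obs"])

  expect_error(call_malignant(sc, b$cells, b$cells$barcode), "overlaps")
})

test_that("planted-gain magnitude never lowers the median score", {
  meds <- vapply(c(1.2, 1.5, 2.0), function(fold) {
    cfg <- synth_config(
      n_genes = 200, n_chromosomes = 4,
      populations = tibble::tibble(
        name = c("m1", "normal epi"), cell_type = "epithelial",
        compartment = c("receiver", "reference"), n_cells = 60L,
        subcluster = c("m1", NA), zone = c("core", "outer"),
        group = c("tumor", "normal"), sample = c("S1", "S0")),
      n_cascades = 0, decoy_priors = 0,
      cnv_segments = tibble::tibble(subcluster = "m1", chrom = 2,
                                    first_gene = 51, n_genes = 40,
                                    fold = fold),
      n_markers = 0, seed = 4)
    b <- generate_synth(cfg)
    prof <- build_cnv_profile(b$counts, b$positions, b$truth$reference_cells)
    sc <- cnv_score(prof)
    median(sc$score[sc$cell %in%
                      b$cells$barcode[!is.na(b$cells$subcluster)]])
  }, numeric(1))
  expect_true(all(diff(meds) >= 0))
})

test_that("planted gains raise residuals inside the segment", {
  cfg <- synth_config(
    n_genes = 200, n_chromosomes = 4,
    populations = tibble::tibble(
      name = c("m1", "normal epi"), cell_type = "epithelial",
      compartment = c("receiver", "reference"), n_cells = 80L,
      subcluster = c("m1", NA), zone = c("core", "outer"),
      group = c("tumor", "normal"), sample = c("S1", "S0")),
    n_cascades = 0, decoy_priors = 0,
    cnv_segments = tibble::tibble(subcluster = "m1", chrom = 2,
                                  first_gene = 51, n_genes = 40, fold = 2.0),
    n_markers = 0, seed = 8)
  b <- generate_synth(cfg)
  prof <- build_cnv_profile(b$counts, b$positions, b$truth$reference_cells,
                            window = 21)
  obs <- rownames(prof$residuals) %in%
    b$cells$barcode[!is.na(b$cells$subcluster)]
  seg_genes <- intersect(sprintf("G%04d", 51:90), colnames(prof$residuals))
  inside <- rowMeans(prof$residuals[obs, seg_genes, drop = FALSE])
  outside <- rowMeans(prof$residuals[obs, setdiff(colnames(prof$residuals),
                                                  seg_genes), drop = FALSE])
  expect_gt(mean(inside) - mean(outside), 0.1)
  mid <- seg_genes[ceiling(length(seg_genes) / 2)]
  expect_gt(mean(prof$residuals[obs, mid]), 0)
})

test_that("subclusters sharing a gain correlate above 0.8", {
  pops <- tibble::tibble(
    name = c("m1", "m2", "normal epi"), cell_type = "epithelial",
    compartment = c("receiver", "receiver", "reference"), n_cells = 80L,
    subcluster = c("m1", "m2", NA), zone = c("core", "front", "outer"),
    group = c("tumor", "tumor", "normal"), sample = "S1")
  cfg <- synth_config(
    n_genes = 200, n_chromosomes = 4, populations = pops,
    n_cascades = 0, decoy_priors = 0,
    cnv_segments = tibble::tibble(subcluster = c("m1", "m2"), chrom = 2,
                                  first_gene = 51, n_genes = 40, fold = 1.8),
    n_markers = 0, seed = 21)
  b <- generate_synth(cfg)
  prof <- build_cnv_profile(b$counts, b$positions, b$truth$reference_cells)
  cc <- cluster_similarity(prof, b$cells)
  expect_identical(dim(cc), c(2L, 2L))
  expect_equal(diag(cc), c(m1 = 1, m2 = 1))
  expect_gt(cc["m1", "m2"], 0.80)
  expect_equal(cc, t(cc))

  # exact negatives correlate at -1
  prof2 <- structure(list(residuals = rbind(a = c(1, 2, 3), b = -c(1, 2, 3)),
                          genes = NULL), class = "cnv_profile")
  colnames(prof2$residuals) <- c("g1", "g2", "g3")
  cells2 <- tibble::tibble(barcode = c("a", "b"), subcluster = c("s1", "s2"))
  cc2 <- cluster_similarity(prof2, cells2)
  expect_equal(cc2["s1", "s2"], -1)
})
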