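#' Expression-derived copy-number profile
#'
#' Builds a smoothed, reference-centered relative-expression profile along
#' genomic position, in the style of expression-based CNV inference:
#' (1) drop genes with mean raw expression below `cutoff` across all cells;
#' (2) log-normalize; (3) center each gene on the reference-cell mean;
#' (4) clamp centered values to `[-3, 3]`; (5) moving-average smooth over
#' `window` genes within each chromosome (the window shrinks at chromosome
#' ends and never crosses a boundary); (6) re-center each cell on its own
#' median; (7) subtract the reference cells' post-smoothing mean profile,
#' so the reference mean residual profile is exactly zero.
#'
#' @param m Raw count matrix (genes x cells).
#' @param positions Gene-position table (see [read_gene_positions()]);
#'   chromosome order is taken from its `chrom` factor levels.
#' @param reference_cells Barcodes of the normal reference population.
#' @param window Odd moving-average width in genes (default 101).
#' @param cutoff Minimum mean raw expression per gene (default 0.1).
#' @param scale_factor Library-size target for the internal normalization.
#' @return A `cnv_profile` object: list with `residuals` (cells x genes),
#'   `genes` (position-ordered tibble), `reference_cells`, `window`,
#'   `cutoff`.
#' @export
build_cnv_profile <- function(m, positions, reference_cells,
                              window = 101, cutoff = 0.1,
                              scale_factor = 1e4) {
  m <- validate_counts(m)
  positions <- validate_gene_positions(positions)
  if (!length(reference_cells)) abort("empty reference cell set")
  reference_cells <- intersect(reference_cells, colnames(m))
  if (!length(reference_cells)) abort("reference cells absent from matrix")
  if (length(reference_cells) >= ncol(m)) {
    abort("reference must be disjoint from at least one observation cell")
  }
  if (window < 1 || window %% 2 == 0) abort("window must be a positive odd count")

  covered <- intersect(rownames(m), positions$gene)
  if (length(covered) < 0.5 * nrow(m)) {
    abort("genomic positions missing for more than 50% of genes")
  }
  mean_expr <- Matrix::rowMeans(m)
  keep <- names(mean_expr)[mean_expr >= cutoff]
  keep <- intersect(keep, covered)
  pos <- positions |>
    dplyr::filter(.data$gene %in% keep) |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene)

  norm <- normalize_counts(m[pos$gene, , drop = FALSE], scale_factor)
  x <- t(as.matrix(norm))                       # cells x genes
  ref_mean <- colMeans(x[reference_cells, , drop = FALSE])
  x <- sweep(x, 2, ref_mean)
  x <- pmin(pmax(x, -3), 3)

  chrom <- as.character(pos$chrom)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    x[, idx] <- .moving_average_rows(x[, idx, drop = FALSE], window)
  }
  x <- x - apply(x, 1, median)
  x <- sweep(x, 2, colMeans(x[reference_cells, , drop = FALSE]))

  structure(list(residuals = x, genes = pos,
                 reference_cells = reference_cells,
                 window = window, cutoff = cutoff),
            class = "cnv_profile")
}

# Row-wise centered moving average with shrinking windows at the ends.
.moving_average_rows <- function(x, window) {
  g <- ncol(x)
  if (window == 1 || g == 1) return(x)
  h <- (window - 1) / 2
  cs <- cbind(0, t(apply(x, 1, cumsum)))
  lo <- pmax(1, seq_len(g) - h)
  hi <- pmin(g, seq_len(g) + h)
  out <- (cs[, hi + 1, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1, each = nrow(x))
  dimnames(out) <- dimnames(x)
  out
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("<cnv_profile> %d cells x %d genes, window %d, cutoff %g\n",
              nrow(x$residuals), ncol(x$residuals), x$window, x$cutoff))
  invisible(x)
}

#' Per-cell cumulative CNV score
#'
#' The cumulative deviation of the profile: by default the sum of squared
#' residuals over all position-ordered genes, so a cell scores 0 iff its
#' residual profile is identically zero. An absolute-sum variant is exposed
#' for sensitivity analyses.
#'
#' @param profile A `cnv_profile`.
#' @param method `"squared"` (default) or `"absolute"`.
#' @return A tibble with columns `cell`, `score`.
#' @export
cnv_score <- function(profile, method = c("squared", "absolute")) {
  method <- match.arg(method)
  r <- profile$residuals
  s <- if (method == "squared") rowSums(r^2) else rowSums(abs(r))
  tibble::tibble(cell = rownames(r), score = unname(s))
}

#' Call malignant subclusters from CNV scores
#'
#' Per subcluster, a one-sided rank-sum test of subcluster scores being
#' greater than the reference scores; a subcluster is malignant when
#' `p < alpha` and its median score exceeds the reference median.
#'
#' @param scores Tibble from [cnv_score()].
#' @param cells Cell table with `barcode` and `subcluster` (cells with `NA`
#'   subcluster are ignored).
#' @param reference_cells Barcodes of the reference population.
#' @param alpha Significance threshold (default 0.05).
#' @param min_cells Minimum subcluster size (default 3).
#' @return A tibble with columns `subcluster`, `n_cells`, `median_score`,
#'   `reference_median`, `p_value`, `is_malignant`.
#' @export
call_malignant <- function(scores, cells, reference_cells, alpha = 0.05,
                           min_cells = 3) {
  cells <- tibble::as_tibble(cells)
  score_of <- setNames(scores$score, scores$cell)
  ref_scores <- score_of[intersect(reference_cells, scores$cell)]
  if (!length(ref_scores)) abort("no reference cells with scores")
  ref_median <- median(ref_scores)

  sub_tab <- cells |>
    dplyr::filter(!is.na(.data$subcluster), .data$barcode %in% scores$cell)
  subs <- sort(unique(sub_tab$subcluster))
  purrr::map_dfr(subs, function(s) {
    bc <- sub_tab$barcode[sub_tab$subcluster == s]
    if (any(bc %in% reference_cells)) {
      abort(sprintf("subcluster '%s' overlaps the reference set", s))
    }
    if (length(bc) < min_cells) {
      abort(sprintf("subcluster '%s' has fewer than %d cells", s, min_cells))
    }
    x <- score_of[bc]
    p <- suppressWarnings(
      wilcox.test(x, ref_scores, alternative = "greater")$p.value)
    tibble::tibble(subcluster = s, n_cells = length(bc),
                   median_score = median(x), reference_median = ref_median,
                   p_value = p,
                   is_malignant = p < alpha && median(x) > ref_median)
  })
}

#' Pairwise subcluster similarity of CNV profiles
#'
#' Spearman correlation between the mean residual profiles of each pair of
#' subclusters. A constant mean profile yields `NA` (undefined correlation),
#' not an error.
#'
#' @param profile A `cnv_profile`.
#' @param cells Cell table with `barcode` and `subcluster`.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
cluster_similarity <- function(profile, cells) {
  cells <- tibble::as_tibble(cells)
  sub_tab <- cells |>
    dplyr::filter(!is.na(.data$subcluster),
                  .data$barcode %in% rownames(profile$residuals))
  subs <- sort(unique(sub_tab$subcluster))
  if (length(subs) < 2) abort("need at least 2 subclusters")
  means <- vapply(subs, function(s) {
    colMeans(profile$residuals[sub_tab$barcode[sub_tab$subcluster == s], ,
                               drop = FALSE])
  }, numeric(ncol(profile$residuals)))
  cc <- suppressWarnings(cor(means, method = "spearman"))
  diag(cc) <- 1
  cc
}
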