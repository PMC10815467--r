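#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact distribution whenever there are no ties and both groups have fewer
#' than 50 observations; otherwise the normal approximation with tie and
#' continuity corrections. This is the test behind one-vs-rest marker
#' screening.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) abort("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1) return(1)   # complete tie
  p <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
  if (is.na(p)) 1 else min(p, 1)
}

#' Seurat-style natural-log fold change
#'
#' `ln(mean(expm1(in)) + 1) - ln(mean(expm1(out)) + 1)`: back-transformed
#' group means with pseudocount 1, on the natural-log scale.
#'
#' @param m Normalized expression matrix (genes x cells).
#' @param in_cells,out_cells Disjoint, non-empty barcode vectors.
#' @param genes Gene symbols to evaluate (default: all rows).
#' @return Named numeric vector of log fold changes.
#' @export
log_fold_change <- function(m, in_cells, out_cells, genes = rownames(m)) {
  if (!length(in_cells) || !length(out_cells)) abort("empty cell group")
  if (length(intersect(in_cells, out_cells))) abort("cell groups overlap")
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    abort(sprintf("gene(s) absent from matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  mi <- m[genes, in_cells, drop = FALSE]
  mo <- m[genes, out_cells, drop = FALSE]
  lfc <- log(Matrix::rowMeans(expm1(mi)) + 1) -
    log(Matrix::rowMeans(expm1(mo)) + 1)
  setNames(as.numeric(lfc), genes)
}

#' Differential-expression screen for a receiver subcluster
#'
#' One-vs-rest Wilcoxon rank-sum screen of a focal subcluster against all
#' other cells of the same compartment (cells sharing the focal cells'
#' `cell_type`). Genes pass with raw `p_value < pval` and
#' `log_fc > logfc`; BH-adjusted p-values are reported alongside.
#'
#' @param m Normalized expression matrix (genes x cells).
#' @param cells Cell table with columns `barcode`, `cell_type`, `subcluster`.
#' @param focal Focal subcluster label; must cover at least 3 cells.
#' @param pval Raw p-value threshold (default 0.05).
#' @param logfc Natural-log fold-change threshold (default 0.15).
#' @param return_all Return all tested genes instead of only those passing.
#' @return A tibble with columns `gene`, `log_fc`, `p_value`, `adj_p`,
#'   `pct_in`, `pct_out`, sorted by p-value then `|log_fc|` descending.
#' @export
deg_screen <- function(m, cells, focal, pval = 0.05, logfc = 0.15,
                       return_all = FALSE) {
  cells <- tibble::as_tibble(cells)
  in_tab <- dplyr::filter(cells, .data$subcluster %in% focal)
  if (nrow(in_tab) == 0) abort(sprintf("focal subcluster '%s' absent", focal))
  if (nrow(in_tab) < 3) abort("focal subcluster has fewer than 3 cells")
  focal_types <- unique(in_tab$cell_type)
  out_tab <- cells[cells$cell_type %in% focal_types &
                     !cells$barcode %in% in_tab$barcode, , drop = FALSE]
  if (nrow(out_tab) == 0) abort("no out-group cells in the focal compartment")
  in_cells <- intersect(in_tab$barcode, colnames(m))
  out_cells <- intersect(out_tab$barcode, colnames(m))

  xi <- as.matrix(m[, in_cells, drop = FALSE])
  xo <- as.matrix(m[, out_cells, drop = FALSE])
  p <- vapply(seq_len(nrow(m)), function(i) rank_sum_test(xi[i, ], xo[i, ]),
              numeric(1))
  res <- tibble::tibble(
    gene = rownames(m),
    log_fc = unname(log_fold_change(m, in_cells, out_cells)),
    p_value = p,
    adj_p = p.adjust(p, method = "BH"),
    pct_in = rowMeans(xi > 0),
    pct_out = rowMeans(xo > 0)
  )
  res <- dplyr::arrange(res, .data$p_value, dplyr::desc(abs(.data$log_fc)))
  if (return_all) res else
    dplyr::filter(res, .data$p_value < pval, .data$log_fc > logfc)
}
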