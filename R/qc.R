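#' Cell quality filtering
#'
#' Keeps cells passing all three quality gates used for droplet scRNA-seq:
#' mitochondrial fraction at most `max_mito_fraction`, total UMI between
#' `umi_min` and `umi_max` (inclusive), and strictly more than `min_genes`
#' detected genes. The gene set is never changed. Per-criterion removal
#' counts are reported via a message.
#'
#' @param m Count matrix (genes x cells).
#' @param max_mito_fraction Maximum mitochondrial UMI fraction (default 0.20).
#' @param umi_min,umi_max Inclusive bounds on total UMI per cell
#'   (defaults 200 and 60000).
#' @param min_genes Exclusive lower bound on detected genes (default 200:
#'   a cell must detect more than 200 genes).
#' @param mito_prefix Prefix identifying mitochondrial genes (default
#'   `"MT-"`, the human convention).
#' @return The filtered count matrix.
#' @export
filter_cells <- function(m, max_mito_fraction = 0.20,
                         umi_min = 200, umi_max = 60000,
                         min_genes = 200, mito_prefix = "MT-") {
  m <- validate_counts(m)
  stopifnot(umi_min <= umi_max,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  total <- Matrix::colSums(m)
  mito_genes <- startsWith(rownames(m), mito_prefix)
  mito <- if (any(mito_genes)) Matrix::colSums(m[mito_genes, , drop = FALSE]) else 0
  mito_frac <- ifelse(total > 0, mito / total, 0)
  detected <- Matrix::colSums(m > 0)

  pass_mito <- mito_frac <= max_mito_fraction
  pass_umi <- total >= umi_min & total <= umi_max
  pass_genes <- detected > min_genes
  keep <- pass_mito & pass_umi & pass_genes

  removed <- c(mito = sum(!pass_mito), umi = sum(!pass_umi),
               genes = sum(!pass_genes))
  inform(sprintf(
    "filter_cells: kept %d/%d cells (failed mito: %d, UMI: %d, detected genes: %d)",
    sum(keep), ncol(m), removed["mito"], removed["umi"], removed["genes"]))
  if (!any(keep)) {
    binding <- names(which.max(removed))
    abort(sprintf("no cells survive quality filtering; binding criterion: %s",
                  c(mito = "mitochondrial fraction", umi = "UMI bounds",
                    genes = "detected-gene minimum")[binding]))
  }
  m[, keep, drop = FALSE]
}

#' Library-size normalization with log transform
#'
#' `value(g, c) = ln(1 + count(g, c) * scale_factor / total(c))`. Cells with
#' zero total counts map to all-zero columns. The zero pattern of the input
#' is preserved exactly.
#'
#' @param m Count matrix (genes x cells).
#' @param scale_factor Positive library-size target (default 10000).
#' @return A sparse matrix of log-normalized expression, same dimnames.
#' @export
normalize_counts <- function(m, scale_factor = 1e4) {
  m <- validate_counts(m)
  stopifnot(scale_factor > 0)
  total <- Matrix::colSums(m)
  fac <- ifelse(total > 0, scale_factor / total, 0)
  out <- m %*% Matrix::Diagonal(x = fac)
  out <- methods::as(out, "CsparseMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m)
  out
}

#' Select highly variable genes
#'
#' Ranks genes by a variance-stabilized dispersion statistic: per-gene
#' variance of values standardized against a loess mean-variance trend,
#' with standardized values clipped at `sqrt(n_cells)` so single outlier
#' cells cannot dominate. Ties are broken lexicographically by symbol, so
#' the ranking is deterministic and invariant to cell-column order.
#'
#' @param m Normalized expression matrix (genes x cells).
#' @param n Number of genes to return (default 2000).
#' @param span Loess span for the mean-variance trend (default 0.5).
#' @return Character vector of the top `n` gene symbols, ranked.
#' @export
select_hvg <- function(m, n = 2000, span = 0.5) {
  if (n <= 0) abort("n must be positive")
  if (n > nrow(m)) abort("n exceeds the number of genes")
  stat <- hvg_statistic(m, span = span)
  ord <- order(-stat$standardized_variance, stat$gene)
  stat$gene[ord][seq_len(n)]
}

#' Per-gene standardized-variance statistic
#'
#' The statistic behind [select_hvg()], returned for all genes.
#'
#' @inheritParams select_hvg
#' @return A tibble with columns `gene`, `mean`, `variance`,
#'   `standardized_variance`.
#' @export
hvg_statistic <- function(m, span = 0.5) {
  x <- as.matrix(m)
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  n_cells <- ncol(x)
  sd_exp <- rep(0, length(mu))
  usable <- v > 0 & mu > 0
  pred <- NULL
  if (sum(usable) >= 5) {
    # the trend fit is allowed to fail or degenerate on toy inputs
    pred <- tryCatch(
      suppressWarnings({
        fit <- loess(log10(v[usable]) ~ log10(mu[usable]), span = span,
                     degree = 2)
        predict(fit)
      }),
      error = function(e) NULL)
    if (!is.null(pred) && !all(is.finite(pred))) pred <- NULL
  }
  # fallback trend when the fit degenerates: Poisson-like variance = mean
  sd_exp[usable] <- if (is.null(pred)) sqrt(mu[usable]) else sqrt(10^pred)
  std_var <- numeric(length(mu))
  clip <- sqrt(n_cells)
  for (i in which(sd_exp > 0)) {
    z <- (x[i, ] - mu[i]) / sd_exp[i]
    z <- pmin(pmax(z, -clip), clip)
    std_var[i] <- var(z)
  }
  tibble::tibble(gene = rownames(m), mean = mu, variance = v,
                 standardized_variance = std_var)
}

#' Per-gene z-scoring (scaling)
#'
#' Centers and scales each gene across cells; genes with zero variance map
#' to zero rows. Kept separate from [normalize_counts()] so downstream
#' stages opt in explicitly.
#'
#' @param m Normalized expression matrix (genes x cells).
#' @param max_value Clip absolute z-scores at this value (default 10).
#' @return A dense matrix of z-scores.
#' @export
scale_genes <- function(m, max_value = 10) {
  x <- as.matrix(m)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  s[s == 0] <- 1
  z <- (x - mu) / s
  pmin(pmax(z, -max_value), max_value)
}
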