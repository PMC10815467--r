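#' Tidy an intercellular network into its edge table
#'
#' @param x An `igrn`.
#' @param ... Unused.
#' @return A tibble with one row per edge: `source`, `target`, `layer`,
#'   `score`, `sender`, `receiver`, `stage`.
#' @export
tidy.igrn <- function(x, ...) {
  dplyr::mutate(x$edges, sender = x$sender, receiver = x$receiver,
                stage = x$stage)
}

#' One-row summary of an intercellular network
#'
#' @param x An `igrn`.
#' @param ... Unused.
#' @return A one-row tibble: stage, per-layer edge counts, node and path
#'   counts.
#' @export
glance.igrn <- function(x, ...) {
  dplyr::mutate(count_signals(x, "all"), stage = x$stage,
                sender = x$sender, receiver = x$receiver) |>
    dplyr::relocate("stage")
}

#' Tidy a CNV profile into long form
#'
#' @param x A `cnv_profile`.
#' @param ... Unused.
#' @return A tibble with columns `cell`, `gene`, `chrom`, `residual`.
#' @export
tidy.cnv_profile <- function(x, ...) {
  r <- x$residuals
  tibble::tibble(
    cell = rep(rownames(r), times = ncol(r)),
    gene = rep(colnames(r), each = nrow(r)),
    chrom = rep(as.character(x$genes$chrom), each = nrow(r)),
    residual = as.numeric(r))
}

#' One-row summary of a CNV profile
#'
#' @param x A `cnv_profile`.
#' @param ... Unused.
#' @return A one-row tibble with dimensions, window, cutoff, and the mean
#'   squared residual.
#' @export
glance.cnv_profile <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$residuals), n_genes = ncol(x$residuals),
                 window = x$window, cutoff = x$cutoff,
                 mean_sq_residual = mean(x$residuals^2))
}
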