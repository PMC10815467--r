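#' Plot an intercellular network as a layered diagram
#'
#' Nodes are arranged in four columns (ligand, receptor, TF, target) and
#' edges drawn left to right, the way the multilayer scaffold is usually
#' shown.
#'
#' @param object An `igrn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.igrn <- function(object, ...) {
  roles <- c("ligand", "receptor", "tf", "target")
  nodes <- object$nodes |>
    dplyr::mutate(layer_x = match(.data$role, roles)) |>
    dplyr::group_by(.data$role) |>
    dplyr::arrange(.data$gene, .by_group = TRUE) |>
    dplyr::mutate(y = seq_len(dplyr::n()) - (dplyr::n() + 1) / 2) |>
    dplyr::ungroup()
  pos <- nodes |> dplyr::select("gene", "role", "layer_x", "y")
  role_of_source <- c("L-R" = "ligand", "R-TF" = "receptor",
                      "TF-target" = "tf")
  role_of_target <- c("L-R" = "receptor", "R-TF" = "tf",
                      "TF-target" = "target")
  edges <- object$edges |>
    dplyr::mutate(role_s = role_of_source[.data$layer],
                  role_t = role_of_target[.data$layer]) |>
    dplyr::left_join(pos, by = c(source = "gene", role_s = "role")) |>
    dplyr::rename(x0 = "layer_x", y0 = "y") |>
    dplyr::left_join(pos, by = c(target = "gene", role_t = "role")) |>
    dplyr::rename(x1 = "layer_x", y1 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$layer),
      alpha = 0.7) +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$layer_x, y = .data$y, label = .data$gene),
      size = 3) +
    ggplot2::scale_x_continuous(breaks = 1:4, labels = roles,
                                limits = c(0.5, 4.5)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s → %s (%s)", object$sender,
                                  object$receiver, object$stage)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Heatmap of a CNV profile
#'
#' Cells (rows, optionally grouped) by position-ordered genes (columns),
#' coloured by smoothed residual, with chromosome boundaries marked.
#'
#' @param object A `cnv_profile`.
#' @param cells Optional cell table with `barcode` and `subcluster` used to
#'   order rows by subcluster.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnv_profile <- function(object, cells = NULL, ...) {
  long <- tidy(object)
  gene_order <- colnames(object$residuals)
  long$gene <- factor(long$gene, levels = gene_order)
  if (!is.null(cells)) {
    cells <- tibble::as_tibble(cells)
    sub <- setNames(cells$subcluster, cells$barcode)
    long$subcluster <- dplyr::coalesce(unname(sub[long$cell]), "reference")
    cell_order <- unique(long$cell[order(long$subcluster, long$cell)])
  } else {
    long$subcluster <- "all"
    cell_order <- unique(long$cell)
  }
  long$cell <- factor(long$cell, levels = cell_order)
  bounds <- cumsum(table(object$genes$chrom))
  ggplot2::ggplot(long, ggplot2::aes(x = as.integer(.data$gene),
                                     y = .data$cell,
                                     fill = .data$residual)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = as.numeric(bounds) + 0.5,
                        linewidth = 0.2, colour = "grey30") +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "genes (genomic order)", y = NULL, fill = "residual") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Volcano plot of a differential-expression screen
#'
#' @param de A DE tibble from [deg_screen()] (ideally with
#'   `return_all = TRUE`).
#' @param pval,logfc Thresholds drawn as guides (defaults 0.05 and 0.15).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, pval = 0.05, logfc = 0.15) {
  de <- dplyr::mutate(de, hit = .data$p_value < pval & .data$log_fc > logfc)
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log_fc,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = logfc, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(pval), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "ln fold change", y = "-log10 p", colour = "passing") +
    ggplot2::theme_minimal()
}

#' Spatial map of K-distances or front calls
#'
#' @param malignant Spatial table of malignant cells with `subcluster`.
#' @param immune Spatial table of the immune population.
#' @param k Neighbor count passed to [kdist()] (default 10).
#' @return A ggplot object: malignant cells coloured by K-distance to
#'   immune, immune cells in grey.
#' @export
plot_kdist_map <- function(malignant, immune, k = 10) {
  kd <- kdist(malignant, immune, k = k)
  mal <- dplyr::left_join(tibble::as_tibble(malignant), kd,
                          by = c(unit_id = "query_cell"))
  ggplot2::ggplot() +
    ggplot2::geom_point(data = tibble::as_tibble(immune),
                        ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "grey70", size = 0.8) +
    ggplot2::geom_point(data = mal,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$kdist), size = 0.9) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = sprintf("kdist (k=%d)", k)) +
    ggplot2::theme_minimal()
}
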