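#' Spot-level cell-type composition scores
#'
#' Scores each spatial unit for each cell type as the mean normalized
#' expression of that type's marker genes, z-scored across units per cell
#' type. With identical units all z-scores are 0.
#'
#' @param st_counts Count matrix (genes x spots).
#' @param spatial Spatial table whose `unit_id` matches the matrix columns.
#' @param markers Named list mapping cell type -> character vector of marker
#'   genes; each set must have at least one gene present in the matrix.
#' @param scale_factor Library-size target for the internal normalization.
#' @return A tibble with columns `unit_id`, `cell_type`, `score`.
#' @export
score_spot_composition <- function(st_counts, spatial, markers,
                                   scale_factor = 1e4) {
  spatial <- tibble::as_tibble(spatial)
  units <- intersect(spatial$unit_id, colnames(st_counts))
  if (!length(units)) abort("no spatial units match matrix columns")
  norm <- normalize_counts(st_counts[, units, drop = FALSE], scale_factor)
  purrr::imap_dfr(markers, function(genes, type) {
    genes <- intersect(toupper(genes), rownames(norm))
    if (!length(genes)) {
      abort(sprintf("no marker genes present in matrix for type '%s'", type))
    }
    raw <- Matrix::colMeans(norm[genes, , drop = FALSE])
    s <- sd(raw)
    z <- if (s > 0) (raw - mean(raw)) / s else rep(0, length(raw))
    tibble::tibble(unit_id = units, cell_type = type, score = unname(z))
  })
}

#' Mean K-nearest distance between spatial populations
#'
#' For each query unit, the mean Euclidean distance to its `k` nearest
#' reference units. Ties in distance are broken by reference order (row
#' order, i.e. unit ID order of the reference table), so results are
#' deterministic.
#'
#' @param query,reference Spatial tables (`unit_id`, `x`, `y`); both
#'   non-empty.
#' @param k Number of nearest reference units (default 10); values above
#'   the reference size are truncated with a warning.
#' @return A tibble with columns `query_cell`, `k`, `kdist`.
#' @export
kdist <- function(query, reference, k = 10) {
  query <- tibble::as_tibble(query)
  reference <- tibble::as_tibble(reference)
  if (!nrow(query) || !nrow(reference)) abort("empty query or reference")
  if (k < 1) abort("k must be at least 1")
  if (k > nrow(reference)) {
    warn(sprintf("k = %d exceeds reference size %d; truncated", k,
                 nrow(reference)))
    k <- nrow(reference)
  }
  d2 <- outer(query$x, reference$x, "-")^2 + outer(query$y, reference$y, "-")^2
  kd <- apply(d2, 1, function(row) {
    mean(sqrt(row[order(row)[seq_len(k)]]))
  })
  tibble::tibble(query_cell = query$unit_id, k = k, kdist = unname(kd))
}

#' Invasive-front calls for malignant subclusters
#'
#' Operationalizes the "leading edge": a malignant subcluster sits at the
#' front when its K-distance-to-immune distribution is significantly lower
#' (one-sided rank-sum, `p < alpha`) than the pooled K-distances of all
#' other malignant subclusters. With a single subcluster there is nothing
#' to compare and calls are reported as `NA`.
#'
#' @param malignant Spatial table of malignant cells with a `subcluster`
#'   column (or `label`, taken as the subcluster).
#' @param immune Spatial table of the immune reference population.
#' @param k Neighbor count for [kdist()] (default 10).
#' @param alpha Significance threshold (default 0.05).
#' @param candidates Optional subcluster subset to restrict front
#'   candidates (e.g. from trajectory-state labels); others are still used
#'   as the comparison pool but reported `NA`.
#' @return A tibble with columns `subcluster`, `n_cells`, `median_kdist`,
#'   `p_value`, `is_front`.
#' @export
call_front <- function(malignant, immune, k = 10, alpha = 0.05,
                       candidates = NULL) {
  malignant <- tibble::as_tibble(malignant)
  if (!"subcluster" %in% names(malignant)) {
    if ("label" %in% names(malignant)) {
      malignant$subcluster <- malignant$label
    } else {
      abort("malignant table needs a 'subcluster' (or 'label') column")
    }
  }
  kd <- kdist(malignant, immune, k = k)
  kd$subcluster <- malignant$subcluster[match(kd$query_cell,
                                              malignant$unit_id)]
  subs <- sort(unique(kd$subcluster))
  single <- length(subs) < 2
  if (single) inform("single subcluster: front calls undefined")
  purrr::map_dfr(subs, function(s) {
    x <- kd$kdist[kd$subcluster == s]
    rest <- kd$kdist[kd$subcluster != s]
    if (single) {
      p <- NA_real_; front <- NA
    } else {
      p <- suppressWarnings(
        wilcox.test(x, rest, alternative = "less")$p.value)
      front <- p < alpha
      if (!is.null(candidates) && !s %in% candidates) front <- NA
    }
    tibble::tibble(subcluster = s, n_cells = length(x),
                   median_kdist = median(x), p_value = p, is_front = front)
  })
}
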