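#' TF-target co-expression scores
#'
#' Scores every (TF, candidate target) pair by the absolute Spearman
#' correlation of their expression across cells; pairs below `min_score`
#' are dropped and self-pairs excluded. Constant genes score 0.
#'
#' @param m Normalized expression matrix (genes x cells), usually already
#'   subset to the receiver population.
#' @param tfs Character vector of TF symbols present in the matrix.
#' @param candidate_targets Character vector of candidate target symbols.
#' @param min_score Minimum absolute correlation retained (default 0.1).
#' @return A tibble with columns `tf`, `target`, `score`.
#' @export
coexpression_scores <- function(m, tfs, candidate_targets, min_score = 0.1) {
  tfs <- intersect(toupper(tfs), rownames(m))
  targets <- intersect(toupper(candidate_targets), rownames(m))
  if (!length(tfs) || !length(targets)) {
    return(tibble::tibble(tf = character(), target = character(),
                          score = numeric()))
  }
  xt <- t(as.matrix(m[tfs, , drop = FALSE]))
  xg <- t(as.matrix(m[targets, , drop = FALSE]))
  cc <- suppressWarnings(cor(xt, xg, method = "spearman"))
  cc[is.na(cc)] <- 0
  out <- tibble::tibble(
    tf = rep(tfs, times = length(targets)),
    target = rep(targets, each = length(tfs)),
    score = abs(as.numeric(cc))
  )
  out |>
    dplyr::filter(.data$tf != .data$target, .data$score >= min_score) |>
    dplyr::arrange(.data$tf, .data$target)
}

#' Prune co-expressed pairs by motif priors
#'
#' Keeps a (TF, target) pair iff it appears in the TF-target priors with
#' motif evidence, groups survivors by TF, and drops TFs with fewer than
#' `min_targets` targets.
#'
#' @param scored_pairs Tibble from [coexpression_scores()].
#' @param priors A `prior_knowledge` object.
#' @param min_targets Minimum targets per retained TF (default 1).
#' @return A `regulon_set`: tibble with columns `tf`, `target`, `score`.
#' @export
prune_by_motif <- function(scored_pairs, priors, min_targets = 1) {
  tft <- dplyr::filter(priors$tft_priors, .data$motif)
  out <- dplyr::inner_join(scored_pairs, tft[, c("tf", "target")],
                           by = c("tf", "target")) |>
    dplyr::group_by(.data$tf) |>
    dplyr::filter(dplyr::n() >= min_targets) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$tf, .data$target)
  structure(out, class = c("regulon_set", class(out)))
}

#' Per-cell regulon activity (area under the recovery curve)
#'
#' For each cell, genes are ranked by descending expression (ties broken
#' lexicographically by symbol) and the recovery curve of each regulon's
#' targets is integrated over the top `ceiling(top_fraction * n_genes)`
#' ranks. The area is normalized so that a regulon whose targets occupy the
#' top ranks scores exactly 1 and one with no target in the window scores 0.
#'
#' @param m Normalized expression matrix (genes x cells).
#' @param regulons A `regulon_set` (or tibble with `tf`, `target`).
#' @param top_fraction Fraction of the ranking integrated (default 0.05).
#' @return A tibble with columns `tf`, `cell`, `auc` (each in `[0, 1]`).
#' @export
aucell_activity <- function(m, regulons, top_fraction = 0.05) {
  if (top_fraction <= 0 || top_fraction > 1) {
    abort("top_fraction must be in (0, 1]")
  }
  genes <- rownames(m)
  n_genes <- length(genes)
  w <- ceiling(top_fraction * n_genes)
  target_sets <- split(regulons$target, regulons$tf)
  target_sets <- lapply(target_sets, function(tg) {
    tg <- intersect(unique(tg), genes)
    if (!length(tg)) abort("regulon has no targets present in the matrix")
    tg
  })
  x <- as.matrix(m)
  lex <- order(genes)        # secondary key: gene symbol
  cells <- colnames(m)
  auc_mat <- matrix(NA_real_, nrow = length(target_sets), ncol = length(cells),
                    dimnames = list(names(target_sets), cells))
  for (j in seq_along(cells)) {
    v <- x[, j]
    ord <- lex[order(-v[lex])]           # stable: expression desc, symbol asc
    top <- genes[ord[seq_len(w)]]
    for (tf in names(target_sets)) {
      auc_mat[tf, j] <- .recovery_auc(top, target_sets[[tf]], w)
    }
  }
  tibble::tibble(
    tf = rep(rownames(auc_mat), times = ncol(auc_mat)),
    cell = rep(colnames(auc_mat), each = nrow(auc_mat)),
    auc = as.numeric(auc_mat)
  )
}

# Area under the step recovery curve evaluated at ranks 1..w, normalized by
# the maximal achievable area for k = min(|targets|, w) targets.
.recovery_auc <- function(top_genes, targets, w) {
  hits <- cumsum(top_genes %in% targets)
  k <- min(length(targets), w)
  max_area <- sum(pmin(seq_len(w), k))
  sum(hits) / max_area
}

#' Identify active TFs in a receiver population
#'
#' A regulon's activity threshold is `mean + 2 * sd` of its AUC across all
#' cells; the TF is active when more than `min_fraction_active` of the
#' receiver cells exceed that threshold.
#'
#' @param activities Tibble from [aucell_activity()].
#' @param receiver_cells Barcodes of the receiver population.
#' @param min_fraction_active Fraction of receiver cells that must exceed
#'   the threshold (default 0.25, exclusive).
#' @return A tibble with columns `tf`, `threshold`, `fraction_active`,
#'   `is_active`.
#' @export
active_tfs <- function(activities, receiver_cells,
                       min_fraction_active = 0.25) {
  parts <- split(tibble::as_tibble(activities), activities$tf)
  purrr::map_dfr(parts, function(a) {
    thr <- mean(a$auc) + 2 * sd(a$auc)
    if (is.na(thr)) thr <- Inf        # single cell: sd undefined
    recv <- a$auc[a$cell %in% receiver_cells]
    frac <- if (length(recv)) mean(recv > thr) else 0
    tibble::tibble(tf = a$tf[1], threshold = thr, fraction_active = frac,
                   is_active = frac > min_fraction_active)
  }) |>
    dplyr::arrange(.data$tf)
}
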