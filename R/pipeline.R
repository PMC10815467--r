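#' Pipeline configuration
#'
#' Resolves every tunable threshold of the pipeline against its default and
#' rejects unknown keys. Inputs are given either as an in-memory
#' `synth_bundle` (`bundle =`) or as file paths (`counts_path` with
#' `counts_format`, `cells_path`, `positions_path`, `lr_path`, `rtf_path`,
#' `tft_path`, optional `spatial_path`).
#'
#' @param ... Named configuration entries overriding the defaults; see
#'   Details.
#' @details Keys and defaults: `senders` (NULL: all sender cell types found),
#'   `receivers` (NULL: all receiver subclusters found), `reference_cells`
#'   (NULL: cells whose `compartment` is `"reference"`), `immune_types`
#'   (NULL: the sender cell types), quality gates `max_mito` (0.2),
#'   `umi_min` (200), `umi_max` (60000), `min_genes` (200), `mito_prefix`
#'   (`"MT-"`); `scale_factor` (1e4); `hvg_n` (2000, capped at the gene
#'   count); CNV `window` (101), `cutoff` (0.1), `cnv_alpha` (0.05); spatial
#'   `k` (10), `front_alpha` (0.05); L-R `n_perm` (1000), `pct_min` (0.10),
#'   `p_lr` (0.05); DE `pval` (0.05), `logfc` (0.15); regulon `min_score`
#'   (0.1), `top_fraction` (0.05), `min_fraction_active` (0.25),
#'   `min_targets` (1); `seed` (1), `out_dir` (NULL: nothing written).
#' @return A `pipeline_config` list with all defaults resolved.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    bundle = NULL,
    counts_path = NULL, counts_format = "mtx_triplet",
    cells_path = NULL, positions_path = NULL,
    lr_path = NULL, rtf_path = NULL, tft_path = NULL, spatial_path = NULL,
    senders = NULL, receivers = NULL,
    reference_cells = NULL, immune_types = NULL,
    max_mito = 0.2, umi_min = 200, umi_max = 60000, min_genes = 200,
    mito_prefix = "MT-",
    scale_factor = 1e4, hvg_n = 2000,
    window = 101, cutoff = 0.1, cnv_alpha = 0.05,
    k = 10, front_alpha = 0.05,
    n_perm = 1000, pct_min = 0.10, p_lr = 0.05,
    pval = 0.05, logfc = 0.15,
    min_score = 0.1, top_fraction = 0.05, min_fraction_active = 0.25,
    min_targets = 1,
    seed = 1L, out_dir = NULL
  )
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, user, keep.null = TRUE)
  structure(cfg, class = "pipeline_config")
}

.load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$bundle)) {
    b <- cfg$bundle
    return(list(counts = b$counts, cells = b$cells, positions = b$positions,
                priors = b$priors, spatial = b$spatial))
  }
  needed <- c("counts_path", "cells_path", "positions_path",
              "lr_path", "rtf_path", "tft_path")
  missing <- needed[vapply(needed, function(k) is.null(cfg[[k]]), logical(1))]
  if (length(missing)) {
    abort(sprintf("configuration missing input key(s): %s",
                  paste(missing, collapse = ", ")))
  }
  cells <- readr::read_tsv(cfg$cells_path, col_types = readr::cols(),
                           progress = FALSE)
  list(
    counts = read_counts(cfg$counts_path, cfg$counts_format),
    cells = cells,
    positions = read_gene_positions(cfg$positions_path),
    priors = read_priors(cfg$lr_path, cfg$rtf_path, cfg$tft_path),
    spatial = if (!is.null(cfg$spatial_path)) read_spatial(cfg$spatial_path)
  )
}

#' Run the full intercellular-network pipeline
#'
#' Executes quality filtering, normalization and HVG selection, CNV
#' profiling with malignancy calls, invasive-front calls (when spatial
#' coordinates are available), and then, per (sender, receiver subcluster)
#' pair: permutation L-R scoring, the receiver DEG screen, regulon inference
#' with activity scoring, preliminary network assembly and regulon/DEG
#' pruning. All stochastic stages derive their seeds from the single
#' configured seed, so reruns are byte-identical.
#'
#' @param config A [pipeline_config()] (or arguments for one).
#' @return An `igrn_pipeline` list: `qc`, `hvg`, `cnv` (profile, scores,
#'   calls, similarity), `front`, and `results` (one entry per
#'   sender/receiver pair with `lr`, `degs`, `regulons`, `tf_activity`,
#'   `preliminary`, `pruned`, `signal_counts`), plus `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  cfg <- config
  inputs <- .load_pipeline_inputs(cfg)
  counts <- inputs$counts
  cells <- tibble::as_tibble(inputs$cells)
  stages <- character()

  # --- qc -------------------------------------------------------------------
  m <- filter_cells(counts, cfg$max_mito, cfg$umi_min, cfg$umi_max,
                    cfg$min_genes, cfg$mito_prefix)
  cells <- dplyr::filter(cells, .data$barcode %in% colnames(m))
  stages <- c(stages, "qc")

  # --- normalize + hvg ------------------------------------------------------
  norm <- normalize_counts(m, cfg$scale_factor)
  hvg <- select_hvg(norm, min(cfg$hvg_n, nrow(norm)))
  stages <- c(stages, "normalize")

  # --- populations ----------------------------------------------------------
  reference_cells <- cfg$reference_cells
  if (is.null(reference_cells) && "compartment" %in% names(cells)) {
    reference_cells <- cells$barcode[cells$compartment == "reference"]
  }
  senders <- cfg$senders
  if (is.null(senders) && "compartment" %in% names(cells)) {
    senders <- unique(cells$cell_type[cells$compartment == "sender"])
  }
  receivers <- cfg$receivers
  if (is.null(receivers)) {
    rc <- if ("compartment" %in% names(cells)) {
      cells[cells$compartment == "receiver", ]
    } else cells
    receivers <- sort(unique(rc$subcluster[!is.na(rc$subcluster)]))
  }
  if (is.null(senders) || !length(senders)) abort("no sender populations")
  if (!length(receivers)) abort("no receiver subclusters")

  # --- cnv ------------------------------------------------------------------
  cnv <- NULL
  if (!is.null(reference_cells) && length(reference_cells)) {
    profile <- build_cnv_profile(m, inputs$positions, reference_cells,
                                 cfg$window, cfg$cutoff, cfg$scale_factor)
    scores <- cnv_score(profile)
    calls <- call_malignant(scores, cells, reference_cells, cfg$cnv_alpha)
    sim <- if (sum(!is.na(unique(cells$subcluster))) >= 2) {
      cluster_similarity(profile, cells)
    }
    cnv <- list(profile = profile, scores = scores, calls = calls,
                similarity = sim)
    stages <- c(stages, "cnv")
  }

  # --- spatial front --------------------------------------------------------
  front <- NULL
  if (!is.null(inputs$spatial)) {
    sp <- dplyr::filter(inputs$spatial, .data$unit_id %in% cells$barcode)
    sub_of <- setNames(cells$subcluster, cells$barcode)
    type_of <- setNames(cells$cell_type, cells$barcode)
    immune_types <- cfg$immune_types %||% senders
    # the front contrast needs every malignant subcluster, not only the
    # receivers selected for network construction
    mal <- sp |>
      dplyr::mutate(subcluster = unname(sub_of[.data$unit_id])) |>
      dplyr::filter(!is.na(.data$subcluster))
    imm <- dplyr::filter(sp, type_of[.data$unit_id] %in% immune_types)
    if (nrow(mal) && nrow(imm)) {
      front <- call_front(mal, imm, cfg$k, cfg$front_alpha)
      stages <- c(stages, "front")
    }
  }

  # --- per sender x receiver ------------------------------------------------
  priors <- inputs$priors
  tf_pool <- unique(priors$tft_priors$tf)
  target_pool <- unique(priors$tft_priors$target)
  results <- list()
  degs_cache <- list()
  reg_cache <- list()
  idx <- 0L
  for (rcv in receivers) {
    receiver_cells <- cells$barcode[!is.na(cells$subcluster) &
                                      cells$subcluster == rcv]
    if (is.null(degs_cache[[rcv]])) {
      degs_cache[[rcv]] <- deg_screen(norm, cells, rcv, cfg$pval, cfg$logfc)
    }
    if (is.null(reg_cache[[rcv]])) {
      scored <- coexpression_scores(norm[, receiver_cells, drop = FALSE],
                                    tf_pool, target_pool, cfg$min_score)
      regulons <- prune_by_motif(scored, priors, cfg$min_targets)
      activity <- if (nrow(regulons)) {
        aucell_activity(norm, regulons, cfg$top_fraction)
      } else {
        tibble::tibble(tf = character(), cell = character(), auc = numeric())
      }
      act <- if (nrow(activity)) {
        active_tfs(activity, receiver_cells, cfg$min_fraction_active)
      } else {
        tibble::tibble(tf = character(), threshold = numeric(),
                       fraction_active = numeric(), is_active = logical())
      }
      reg_cache[[rcv]] <- list(
        regulons = regulons,
        tf_activity = act,
        active_regulons = dplyr::filter(
          regulons, .data$tf %in% act$tf[act$is_active])
      )
    }
    for (snd in senders) {
      idx <- idx + 1L
      lr <- lr_score(norm, cells, snd, rcv, priors, cfg$n_perm,
                     seed = cfg$seed + 101L * idx, pct_min = cfg$pct_min)
      prelim <- build_preliminary(norm, cells, snd, rcv, priors, lr,
                                  cfg$p_lr, cfg$pct_min)
      pruned <- prune_igrn(prelim, reg_cache[[rcv]]$active_regulons,
                           degs_cache[[rcv]])
      results[[paste(snd, rcv, sep = "->")]] <- list(
        sender = snd, receiver = rcv, lr = lr,
        degs = degs_cache[[rcv]],
        regulons = reg_cache[[rcv]]$regulons,
        tf_activity = reg_cache[[rcv]]$tf_activity,
        preliminary = prelim, pruned = pruned,
        signal_counts = dplyr::bind_rows(
          dplyr::mutate(count_signals(prelim, "all"), stage = "preliminary"),
          dplyr::mutate(count_signals(pruned, "all"), stage = "pruned")
        ) |> dplyr::relocate("stage")
      )
    }
  }
  stages <- c(stages, "lr", "de", "regulon", "igrn")

  manifest <- list(
    package = "igrnet",
    version = as.character(utils::packageVersion("igrnet")),
    seed = cfg$seed,
    stages = stages,
    senders = senders, receivers = receivers,
    thresholds = cfg[c("max_mito", "umi_min", "umi_max", "min_genes",
                       "scale_factor", "hvg_n", "window", "cutoff",
                       "cnv_alpha", "k", "front_alpha", "n_perm", "pct_min",
                       "p_lr", "pval", "logfc", "min_score", "top_fraction",
                       "min_fraction_active", "min_targets")]
  )
  out <- structure(list(qc = m, normalized = norm, hvg = hvg, cells = cells,
                        cnv = cnv, front = front, results = results,
                        manifest = manifest, config = cfg),
                   class = "igrn_pipeline")
  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(out, cfg$out_dir)
  out
}

.safe_label <- function(x) gsub("[^A-Za-z0-9]+", "-", x)

.write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble::tibble(gene = out$hvg), file.path(dir, "hvg.tsv"),
                   progress = FALSE)
  if (!is.null(out$cnv)) {
    readr::write_tsv(out$cnv$scores, file.path(dir, "cnv_scores.tsv"),
                     progress = FALSE)
    readr::write_tsv(out$cnv$calls, file.path(dir, "malignancy_calls.tsv"),
                     progress = FALSE)
  }
  if (!is.null(out$front)) {
    readr::write_tsv(out$front, file.path(dir, "front_calls.tsv"),
                     progress = FALSE)
  }
  counts_all <- list()
  for (res in out$results) {
    tag <- paste(.safe_label(res$sender), .safe_label(res$receiver), sep = "_")
    readr::write_tsv(res$lr, file.path(dir, paste0("lr_", tag, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(res$degs,
                     file.path(dir, paste0("degs_",
                                           .safe_label(res$receiver), ".tsv")),
                     progress = FALSE)
    readr::write_tsv(res$regulons,
                     file.path(dir, paste0("regulons_",
                                           .safe_label(res$receiver), ".tsv")),
                     progress = FALSE)
    write_igrn(res$preliminary,
               file.path(dir, paste0("preliminary_", tag, ".tsv")), "edge_tsv")
    write_igrn(res$pruned,
               file.path(dir, paste0("pruned_", tag, ".tsv")), "edge_tsv")
    write_igrn(res$pruned,
               file.path(dir, paste0("pruned_", tag, ".json")), "json")
    counts_all[[tag]] <- dplyr::mutate(res$signal_counts,
                                       sender = res$sender,
                                       receiver = res$receiver)
  }
  readr::write_tsv(dplyr::bind_rows(counts_all),
                   file.path(dir, "signal_counts.tsv"), progress = FALSE)
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.igrn_pipeline <- function(x, ...) {
  cat(sprintf("<igrn_pipeline> %d cells after QC, %d sender/receiver pair(s)\n",
              ncol(x$qc), length(x$results)))
  for (nm in names(x$results)) {
    sc <- x$results[[nm]]$signal_counts
    cat(sprintf("  %s: %d preliminary -> %d pruned edges\n", nm,
                sc$total[sc$stage == "preliminary"],
                sc$total[sc$stage == "pruned"]))
  }
  invisible(x)
}

#' Edge-level recovery metrics against planted truth
#'
#' Compares a network's edge set with a reference edge table on
#' (source, target, layer) tuples.
#'
#' @param net An `igrn` or an edge tibble (or list of either; edge sets are
#'   unioned).
#' @param truth_edges Tibble with columns `source`, `target`, `layer`.
#' @return A one-row tibble: `n_true`, `n_called`, `n_hit`, `recall`,
#'   `precision`.
#' @export
recovery_metrics <- function(net, truth_edges) {
  as_edges <- function(x) if (inherits(x, "igrn")) x$edges else x
  if (inherits(net, "igrn") || is.data.frame(net)) net <- list(net)
  edges <- dplyr::distinct(
    dplyr::bind_rows(lapply(net, as_edges))[, c("source", "target", "layer")])
  truth <- dplyr::distinct(truth_edges[, c("source", "target", "layer")])
  hit <- nrow(dplyr::inner_join(edges, truth,
                                by = c("source", "target", "layer")))
  tibble::tibble(
    n_true = nrow(truth), n_called = nrow(edges), n_hit = hit,
    recall = if (nrow(truth)) hit / nrow(truth) else NA_real_,
    precision = if (nrow(edges)) hit / nrow(edges) else NA_real_)
}
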