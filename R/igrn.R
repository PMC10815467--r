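#' Construct an intercellular network object
#'
#' Low-level constructor for the directed multilayer network chaining a
#' sender cell's ligand to a receiver cell's receptor, transcription factor
#' and target genes.
#'
#' @param nodes Tibble with columns `gene`, `role`
#'   (`ligand`/`receptor`/`tf`/`target`).
#' @param edges Tibble with columns `source`, `target`, `layer`
#'   (`L-R`/`R-TF`/`TF-target`), `score`.
#' @param sender,receiver Population labels.
#' @param stage `"preliminary"` or `"pruned"`.
#' @param validate Drop nodes/edges not on a complete 4-layer path
#'   (default `TRUE`).
#' @return An `igrn` object.
#' @export
new_igrn <- function(nodes, edges, sender, receiver,
                     stage = c("preliminary", "pruned"), validate = TRUE) {
  stage <- match.arg(stage, c("preliminary", "pruned"))
  if (is.null(nodes)) nodes <- tibble::tibble(gene = character(),
                                              role = character())
  net <- structure(
    list(nodes = tibble::as_tibble(nodes), edges = tibble::as_tibble(edges),
         sender = sender, receiver = receiver, stage = stage),
    class = "igrn")
  if (validate) validate_igrn(net) else net
}

#' Validate an intercellular network
#'
#' Enforces the structural contract: every retained node and edge lies on at
#' least one complete ligand->receptor->TF->target path; edge layers are
#' consistent with endpoint roles; nodes are deduplicated and sorted.
#'
#' @param net An `igrn` object.
#' @return The validated (possibly smaller) `igrn`.
#' @export
validate_igrn <- function(net) {
  e <- net$edges
  lr <- e[e$layer == "L-R", , drop = FALSE]
  rtf <- e[e$layer == "R-TF", , drop = FALSE]
  tft <- e[e$layer == "TF-target", , drop = FALSE]
  bad <- setdiff(unique(e$layer), c("L-R", "R-TF", "TF-target"))
  if (length(bad)) abort(sprintf("unknown edge layer(s): %s",
                                 paste(bad, collapse = ", ")))
  # keep only edges on a complete 4-layer path
  rtf <- rtf[rtf$source %in% lr$target & rtf$target %in% tft$source, ,
             drop = FALSE]
  tft <- tft[tft$source %in% rtf$target, , drop = FALSE]
  rtf <- rtf[rtf$target %in% tft$source, , drop = FALSE]
  lr <- lr[lr$target %in% rtf$source, , drop = FALSE]
  edges <- dplyr::bind_rows(lr, rtf, tft) |>
    dplyr::distinct() |>
    dplyr::arrange(factor(.data$layer, c("L-R", "R-TF", "TF-target")),
                   .data$source, .data$target)
  nodes <- .nodes_from_edges(edges)
  structure(list(nodes = nodes, edges = edges, sender = net$sender,
                 receiver = net$receiver, stage = net$stage),
            class = "igrn")
}

#' @export
print.igrn <- function(x, ...) {
  cnt <- count_signals(x)
  cat(sprintf(
    "<igrn %s> %s -> %s: %d nodes; edges L-R %d, R-TF %d, TF-target %d (total %d)\n",
    x$stage, x$sender, x$receiver, nrow(x$nodes),
    cnt$lr, cnt$rtf, cnt$tf_target, cnt$total))
  invisible(x)
}

#' Permutation-scored ligand-receptor interactions
#'
#' For every prior L-R pair passing the expression gate (ligand expressed in
#' more than `pct_min` of sender cells and receptor in more than `pct_min`
#' of receiver cells), the interaction score is the mean of the ligand's
#' mean normalized expression in the sender and the receptor's mean in the
#' receiver. Significance comes from jointly permuting the sender/receiver
#' labels across the pooled cells: `p = (1 + #[perm >= obs]) / (n_perm + 1)`.
#'
#' @param m Normalized expression matrix (genes x cells).
#' @param cells Cell table (`barcode`, `cell_type`, `subcluster`).
#' @param sender Sender population label (matched against `cell_type`).
#' @param receiver Receiver label (matched against `subcluster` if present
#'   there, else `cell_type`).
#' @param priors A `prior_knowledge` object.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the permutation stream is local to this call.
#' @param pct_min Expression gate: fraction of cells with nonzero counts
#'   (default 0.10, exclusive).
#' @param min_cells Minimum population size (default 10).
#' @return A tibble with columns `ligand`, `receptor`, `sender`, `receiver`,
#'   `score`, `p_value`; empty (with a warning) when no pair passes the gate.
#' @export
lr_score <- function(m, cells, sender, receiver, priors, n_perm = 1000,
                     seed = 1L, pct_min = 0.10, min_cells = 10) {
  cells <- tibble::as_tibble(cells)
  sender_cells <- cells$barcode[cells$cell_type %in% sender]
  receiver_cells <- .match_population(cells, receiver)
  sender_cells <- intersect(sender_cells, colnames(m))
  receiver_cells <- intersect(receiver_cells, colnames(m))
  if (length(sender_cells) < min_cells || length(receiver_cells) < min_cells) {
    abort(sprintf("sender/receiver need at least %d cells each", min_cells))
  }
  pairs <- priors$lr_pairs |>
    dplyr::filter(.data$ligand %in% rownames(m),
                  .data$receptor %in% rownames(m))
  if (nrow(pairs) == 0) {
    warn("no prior L-R pair with both genes in the matrix")
    return(.empty_lr(sender, receiver))
  }
  pct_l <- Matrix::rowMeans(m[pairs$ligand, sender_cells, drop = FALSE] > 0)
  pct_r <- Matrix::rowMeans(m[pairs$receptor, receiver_cells, drop = FALSE] > 0)
  pairs <- pairs[pct_l > pct_min & pct_r > pct_min, , drop = FALSE]
  if (nrow(pairs) == 0) {
    warn("no prior L-R pair passes the expression gate")
    return(.empty_lr(sender, receiver))
  }
  ligs <- unique(pairs$ligand)
  recs <- unique(pairs$receptor)
  mean_l <- Matrix::rowMeans(m[ligs, sender_cells, drop = FALSE])
  mean_r <- Matrix::rowMeans(m[recs, receiver_cells, drop = FALSE])
  obs <- (mean_l[pairs$ligand] + mean_r[pairs$receptor]) / 2

  pool <- c(sender_cells, receiver_cells)
  ns <- length(sender_cells)
  L <- as.matrix(m[ligs, pool, drop = FALSE])
  R <- as.matrix(m[recs, pool, drop = FALSE])
  ge <- withr::with_seed(seed, {
    counts <- rep(0L, nrow(pairs))
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(pool))
      s_idx <- idx[seq_len(ns)]
      r_idx <- idx[-seq_len(ns)]
      ml <- rowMeans(L[, s_idx, drop = FALSE])
      mr <- rowMeans(R[, r_idx, drop = FALSE])
      perm <- (ml[pairs$ligand] + mr[pairs$receptor]) / 2
      counts <- counts + as.integer(perm >= obs)
    }
    counts
  })
  tibble::tibble(ligand = pairs$ligand, receptor = pairs$receptor,
                 sender = sender, receiver = receiver,
                 score = unname(obs),
                 p_value = (1 + ge) / (n_perm + 1)) |>
    dplyr::arrange(.data$p_value, .data$ligand, .data$receptor)
}

.match_population <- function(cells, label) {
  if ("subcluster" %in% names(cells) &&
      any(!is.na(cells$subcluster) & cells$subcluster %in% label)) {
    cells$barcode[!is.na(cells$subcluster) & cells$subcluster %in% label]
  } else {
    cells$barcode[cells$cell_type %in% label]
  }
}

.empty_lr <- function(sender, receiver) {
  tibble::tibble(ligand = character(), receptor = character(),
                 sender = character(), receiver = character(),
                 score = numeric(), p_value = numeric())
}

#' Assemble the preliminary intercellular network
#'
#' Ligands are prior ligands significant in the permutation L-R screen
#' (`p < p_lr`); receptors their prior partners expressed in more than
#' `pct_min` of receiver cells; TFs the prior R-TF partners of selected
#' receptors expressed in the receiver; targets the prior TF-target partners
#' of selected TFs. Edges are assembled layer by layer and any node not on a
#' complete 4-layer path is removed.
#'
#' @param m Normalized expression matrix (genes x cells).
#' @param cells Cell table.
#' @param sender Sender population label.
#' @param receiver_subcluster Receiver subcluster label.
#' @param priors A `prior_knowledge` object.
#' @param lr L-R score tibble from [lr_score()].
#' @param p_lr Significance gate on L-R p-values (default 0.05).
#' @param pct_min Receiver expression gate (default 0.10, exclusive).
#' @return An `igrn` with `stage = "preliminary"` (possibly empty; the first
#'   empty layer is reported via a message).
#' @export
build_preliminary <- function(m, cells, sender, receiver_subcluster, priors,
                              lr, p_lr = 0.05, pct_min = 0.10) {
  cells <- tibble::as_tibble(cells)
  receiver_cells <- intersect(.match_population(cells, receiver_subcluster),
                              colnames(m))
  empty <- function(layer) {
    inform(sprintf("build_preliminary: empty %s layer", layer))
    new_igrn(tibble::tibble(gene = character(), role = character()),
             tibble::tibble(source = character(), target = character(),
                            layer = character(), score = numeric()),
             sender, receiver_subcluster, "preliminary", validate = FALSE)
  }
  lr_sig <- dplyr::filter(lr, .data$p_value < p_lr)
  if (nrow(lr_sig) == 0) return(empty("ligand"))

  expressed <- function(genes) {
    genes <- intersect(genes, rownames(m))
    if (!length(genes)) return(character())
    pct <- Matrix::rowMeans(m[genes, receiver_cells, drop = FALSE] > 0)
    genes[pct > pct_min]
  }
  receptors <- expressed(unique(lr_sig$receptor))
  if (!length(receptors)) return(empty("receptor"))
  lr_edges <- lr_sig |>
    dplyr::filter(.data$receptor %in% receptors) |>
    dplyr::transmute(source = .data$ligand, target = .data$receptor,
                     layer = "L-R", score = .data$score)

  rtf <- priors$rtf_links |> dplyr::filter(.data$receptor %in% receptors)
  tfs <- expressed(unique(rtf$tf))
  if (!length(tfs)) return(empty("tf"))
  rtf_edges <- rtf |>
    dplyr::filter(.data$tf %in% tfs) |>
    dplyr::transmute(source = .data$receptor, target = .data$tf,
                     layer = "R-TF", score = NA_real_)

  tft <- priors$tft_priors |> dplyr::filter(.data$tf %in% tfs)
  if (nrow(tft) == 0) return(empty("target"))
  tft_edges <- tft |>
    dplyr::transmute(source = .data$tf, target = .data$target,
                     layer = "TF-target", score = NA_real_)

  edges <- dplyr::bind_rows(lr_edges, rtf_edges, tft_edges)
  net <- new_igrn(.nodes_from_edges(edges), edges, sender,
                  receiver_subcluster, "preliminary", validate = TRUE)
  if (nrow(net$edges) == 0) inform("build_preliminary: no complete path")
  net
}

#' Prune a preliminary network by regulons and DEGs
#'
#' Keeps a TF node iff it is an active-regulon TF; keeps a TF-target edge
#' iff the pair belongs to that TF's motif-pruned regulon and the target
#' passed the receiver DEG screen; then removes everything no longer on a
#' complete 4-layer path. The pruned edge set is always a subset of the
#' preliminary edge set.
#'
#' @param net A preliminary `igrn`.
#' @param regulons A `regulon_set` restricted to active TFs (e.g.
#'   [prune_by_motif()] output filtered by [active_tfs()]).
#' @param degs DEG tibble from [deg_screen()] (its `gene` column is used).
#' @return An `igrn` with `stage = "pruned"`.
#' @export
prune_igrn <- function(net, regulons, degs) {
  stopifnot(inherits(net, "igrn"))
  keep_tfs <- unique(regulons$tf)
  deg_genes <- unique(degs$gene)
  e <- net$edges
  reg_key <- paste(regulons$tf, regulons$target)
  keep <- rep(TRUE, nrow(e))
  is_tft <- e$layer == "TF-target"
  keep[is_tft] <- paste(e$source[is_tft], e$target[is_tft]) %in% reg_key &
    e$target[is_tft] %in% deg_genes
  is_rtf <- e$layer == "R-TF"
  keep[is_rtf] <- e$target[is_rtf] %in% keep_tfs
  pruned <- net
  pruned$edges <- e[keep, , drop = FALSE]
  pruned$stage <- "pruned"
  validate_igrn(pruned)
}

#' Enumerate complete ligand->receptor->TF->target paths
#'
#' @param net An `igrn`.
#' @return A tibble with columns `ligand`, `receptor`, `tf`, `target`, in
#'   deterministic lexicographic order.
#' @export
extract_paths <- function(net) {
  e <- net$edges
  lr <- e[e$layer == "L-R", c("source", "target")]
  rtf <- e[e$layer == "R-TF", c("source", "target")]
  tft <- e[e$layer == "TF-target", c("source", "target")]
  names(lr) <- c("ligand", "receptor")
  names(rtf) <- c("receptor", "tf")
  names(tft) <- c("tf", "target")
  if (!nrow(lr) || !nrow(rtf) || !nrow(tft)) {
    return(tibble::tibble(ligand = character(), receptor = character(),
                          tf = character(), target = character()))
  }
  lr |>
    dplyr::inner_join(rtf, by = "receptor", relationship = "many-to-many") |>
    dplyr::inner_join(tft, by = "tf", relationship = "many-to-many") |>
    dplyr::distinct() |>
    dplyr::arrange(.data$ligand, .data$receptor, .data$tf, .data$target)
}

#' Count signals per network layer
#'
#' @param net An `igrn`.
#' @param what Count `"edges"` (default; one row) or also report nodes and
#'   paths with `what = "all"`.
#' @return For `"edges"`, a one-row tibble `lr`, `rtf`, `tf_target`,
#'   `total`; for `"all"`, the same plus `n_nodes` and `n_paths`.
#' @export
count_signals <- function(net, what = c("edges", "all")) {
  what <- match.arg(what)
  e <- net$edges
  out <- tibble::tibble(
    lr = sum(e$layer == "L-R"),
    rtf = sum(e$layer == "R-TF"),
    tf_target = sum(e$layer == "TF-target"),
    total = nrow(e)
  )
  if (what == "all") {
    out$n_nodes <- nrow(net$nodes)
    out$n_paths <- nrow(extract_paths(net))
  }
  out
}
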