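#' Configuration for the synthetic single-cell generator
#'
#' Builds the full study design emulated by [generate_synth()]: negative
#' binomial counts with lognormal gene means, two immune sender populations,
#' two malignant receiver subclusters plus a normal epithelial reference,
#' planted ligand->receptor->TF->target cascades whose receiver genes are
#' co-driven by a per-cell latent activity factor, contiguous copy-number
#' gain segments, per-population marker genes, decoy prior edges carrying no
#' signal, and a disc/annulus/ring spatial layout (core tumor, invasive
#' front, surrounding immune ring).
#'
#' @param n_genes Number of genes (default 600), split evenly over
#'   `n_chromosomes`.
#' @param n_chromosomes Number of chromosomes (default 6).
#' @param populations Tibble with columns `name`, `cell_type`, `compartment`
#'   (`sender`/`receiver`/`reference`), `n_cells`, `subcluster` (NA outside
#'   the receiver compartment), `zone` (`core`/`front`/`immune`/`outer`),
#'   `group`, `sample`. Default: macrophage and T-cell senders (150 each),
#'   receiver subclusters m1 (core) and m2 (front) of 150 cells, and a
#'   150-cell normal epithelial reference.
#' @param n_cascades Planted cascades (default 5); senders alternate over
#'   the sender populations and every cascade lands in `cascade_receiver`.
#' @param targets_per_cascade Targets per planted TF (default 3).
#' @param cascade_receiver Receiver subcluster for planted cascades
#'   (default `"m1"`).
#' @param effect Cascade effect size: mean natural-log fold shift of planted
#'   genes (default 1.0). Ligands shift deterministically by `exp(effect)`
#'   in their sender; receiver-side genes shift by `exp(2 * effect)` in the
#'   latent-active half of receiver cells, so the mean log shift is
#'   `effect`.
#' @param latent_fraction Fraction of receiver cells in the latent-active
#'   state (default 0.5).
#' @param decoy_priors Number of decoy prior edges (default 20): hanging
#'   TF-target decoys attached to planted TFs plus complete decoy chains,
#'   all over genes carrying no differential signal.
#' @param cnv_segments Tibble with columns `subcluster`, `chrom`,
#'   `first_gene`, `n_genes`, `fold`. Default: a 1.8-fold gain over 60
#'   contiguous genes on chromosome 2 for m1 and chromosome 4 for m2.
#' @param dispersion Negative-binomial dispersion (default 0.3; NB size is
#'   `1/dispersion`).
#' @param base_meanlog,base_sdlog Lognormal parameters of baseline gene
#'   means (defaults 0 and 1).
#' @param planted_base_mean Baseline mean of planted/decoy/marker genes
#'   (default 3, so expression-fraction gates behave realistically).
#' @param n_markers Marker genes per population (default 5), shifted by
#'   `exp(marker_effect)` in their population.
#' @param marker_effect Marker log-fold shift (default 1.0).
#' @param spatial List: `core_radius` (default 3), `front_width` (2),
#'   `immune_width` (2), `layout` (`"rings"` or `"uniform"`).
#' @param seed Mandatory integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_genes = 600,
                         n_chromosomes = 6,
                         populations = NULL,
                         n_cascades = 5,
                         targets_per_cascade = 3,
                         cascade_receiver = "m1",
                         effect = 1.0,
                         latent_fraction = 0.5,
                         decoy_priors = 20,
                         cnv_segments = NULL,
                         dispersion = 0.3,
                         base_meanlog = 0,
                         base_sdlog = 1,
                         planted_base_mean = 3,
                         n_markers = 5,
                         marker_effect = 1.0,
                         spatial = list(),
                         seed = NULL) {
  if (is.null(seed)) abort("synth_config: seed is mandatory")
  if (is.null(populations)) {
    populations <- tibble::tribble(
      ~name,         ~cell_type,   ~compartment, ~n_cells, ~subcluster, ~zone,   ~group,   ~sample,
      "macrophage",  "macrophage", "sender",     150L,     NA,          "immune", "tumor",  "S1",
      "T cells",     "T cells",    "sender",     150L,     NA,          "immune", "tumor",  "S1",
      "m1",          "epithelial", "receiver",   150L,     "m1",        "core",   "tumor",  "S1",
      "m2",          "epithelial", "receiver",   150L,     "m2",        "front",  "tumor",  "S1",
      "normal epi",  "epithelial", "reference",  150L,     NA,          "outer",  "normal", "S0")
  }
  populations <- tibble::as_tibble(populations)
  per_chr <- n_genes %/% n_chromosomes
  if (is.null(cnv_segments)) {
    subs <- populations$subcluster[populations$compartment == "receiver"]
    subs <- subs[!is.na(subs)]
    cnv_segments <- tibble::tibble(
      subcluster = subs,
      chrom = pmin(seq_along(subs) * 2, n_chromosomes),
      fold = 1.8
    )
    cnv_segments$first_gene <- (cnv_segments$chrom - 1) * per_chr + 1
    cnv_segments$n_genes <- min(60L, per_chr)
  }
  spatial <- modifyList(list(core_radius = 3, front_width = 2,
                             immune_width = 2, layout = "rings"), spatial)
  cfg <- list(n_genes = n_genes, n_chromosomes = n_chromosomes,
              populations = populations, n_cascades = n_cascades,
              targets_per_cascade = targets_per_cascade,
              cascade_receiver = cascade_receiver, effect = effect,
              latent_fraction = latent_fraction, decoy_priors = decoy_priors,
              cnv_segments = tibble::as_tibble(cnv_segments),
              dispersion = dispersion, base_meanlog = base_meanlog,
              base_sdlog = base_sdlog,
              planted_base_mean = planted_base_mean, n_markers = n_markers,
              marker_effect = marker_effect, spatial = spatial,
              seed = as.integer(seed))
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic single-cell bundle with ground truth
#'
#' Emits every input the pipeline needs — counts, cell table, gene
#' positions, prior knowledge, spatial coordinates — plus the planted
#' ground truth. Output is byte-identical for identical config (the seed is
#' part of the config).
#'
#' @param config A [synth_config()].
#' @return A `synth_bundle`: list with elements `counts`, `cells`,
#'   `positions`, `priors`, `spatial`, `truth`, `config`.
#' @export
generate_synth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, .generate_synth_impl(config))
}

.generate_synth_impl <- function(cfg) {
  n_genes <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(n_genes))
  per_chr <- n_genes %/% cfg$n_chromosomes
  chrom_of <- pmin((seq_len(n_genes) - 1) %/% per_chr + 1, cfg$n_chromosomes)
  within <- seq_len(n_genes) - (chrom_of - 1) * per_chr
  positions <- tibble::tibble(
    gene = genes,
    chrom = factor(paste0("chr", chrom_of),
                   levels = paste0("chr", seq_len(cfg$n_chromosomes))),
    start = (within - 1) * 10000 + 1,
    end = (within - 1) * 10000 + 1000
  )

  pops <- cfg$populations
  n_cells <- sum(pops$n_cells)
  cells <- purrr::pmap_dfr(pops, function(name, cell_type, compartment,
                                          n_cells, subcluster, zone, group,
                                          sample, ...) {
    tibble::tibble(population = name, cell_type = cell_type,
                   compartment = compartment,
                   subcluster = if (is.na(subcluster)) NA_character_
                                else subcluster,
                   zone = zone, group = group, sample = sample,
                   barcode = NA_character_, n = seq_len(n_cells))
  })
  cells$barcode <- sprintf("cell%05d", seq_len(nrow(cells)))
  cells$n <- NULL

  # ---- gene role allocation (from the top of the index range downward) ----
  alloc <- .allocate_genes(cfg, genes)

  # ---- expected counts -----------------------------------------------------
  base_mean <- rlnorm(n_genes, cfg$base_meanlog, cfg$base_sdlog)
  special <- unique(c(alloc$cascades$ligand, alloc$cascades$receptor,
                      alloc$cascades$tf, unlist(alloc$cascades$targets),
                      alloc$decoy_genes, alloc$markers$gene))
  base_mean[match(special, genes)] <- cfg$planted_base_mean
  mu <- matrix(base_mean, n_genes, nrow(cells),
               dimnames = list(genes, cells$barcode))

  # markers: deterministic shift in their population
  for (i in seq_len(nrow(alloc$markers))) {
    mk <- alloc$markers[i, ]
    idx <- cells$population == mk$population
    mu[mk$gene, idx] <- mu[mk$gene, idx] * exp(cfg$marker_effect)
  }

  # cascades: ligand up in sender; receiver genes driven by a latent factor
  latent <- list()
  for (i in seq_len(nrow(alloc$cascades))) {
    cs <- alloc$cascades[i, ]
    send_idx <- cells$population == cs$sender
    mu[cs$ligand, send_idx] <- mu[cs$ligand, send_idx] * exp(cfg$effect)
    recv_idx <- which(!is.na(cells$subcluster) &
                        cells$subcluster == cs$receiver)
    a <- rbinom(length(recv_idx), 1, cfg$latent_fraction)
    latent[[cs$name]] <- setNames(a, cells$barcode[recv_idx])
    gset <- c(cs$receptor, cs$tf, cs$targets[[1]])
    mult <- exp(2 * cfg$effect * a)
    mu[gset, recv_idx] <- mu[gset, recv_idx, drop = FALSE] *
      rep(mult, each = length(gset))
  }

  # CNV gains over contiguous position-ordered genes
  if (nrow(cfg$cnv_segments)) {
    for (i in seq_len(nrow(cfg$cnv_segments))) {
      sg <- cfg$cnv_segments[i, ]
      gidx <- seq(sg$first_gene, length.out = sg$n_genes)
      cidx <- which(!is.na(cells$subcluster) &
                      cells$subcluster == sg$subcluster)
      mu[gidx, cidx] <- mu[gidx, cidx, drop = FALSE] * sg$fold
    }
  }

  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")

  # ---- spatial layout ------------------------------------------------------
  sp <- cfg$spatial
  r_core <- sp$core_radius
  r_front <- r_core + sp$front_width
  r_imm <- r_front + sp$immune_width
  band_of <- list(core = c(0, r_core), front = c(r_core, r_front),
                  immune = c(r_front, r_imm), outer = c(r_imm + 1, r_imm + 3))
  xy <- matrix(NA_real_, nrow(cells), 2)
  for (z in names(band_of)) {
    idx <- which(cells$zone == z)
    if (!length(idx)) next
    band <- if (sp$layout == "uniform") c(0, r_imm) else band_of[[z]]
    r <- sqrt(runif(length(idx), band[1]^2, band[2]^2))
    th <- runif(length(idx), 0, 2 * pi)
    xy[idx, ] <- cbind(r * cos(th), r * sin(th))
  }
  spatial <- tibble::tibble(unit_id = cells$barcode, x = xy[, 1], y = xy[, 2],
                            label = cells$cell_type)

  # ---- priors --------------------------------------------------------------
  cas <- alloc$cascades
  lr <- tibble::tibble(ligand = cas$ligand, receptor = cas$receptor)
  rtf <- tibble::tibble(receptor = cas$receptor, tf = cas$tf)
  tft <- purrr::pmap_dfr(cas, function(tf, targets, ...) {
    tibble::tibble(tf = tf, target = targets)
  })
  dec <- alloc$decoys
  priors <- prior_knowledge(
    dplyr::bind_rows(lr, dec$lr),
    dplyr::bind_rows(rtf, dec$rtf),
    dplyr::bind_rows(tft, dec$tft)
  )

  truth <- list(
    cascades = cas,
    cascade_edges = .cascade_edges(cas),
    decoy_edges = dplyr::bind_rows(
      dplyr::transmute(dec$lr, source = .data$ligand,
                       target = .data$receptor, layer = "L-R"),
      dplyr::transmute(dec$rtf, source = .data$receptor, target = .data$tf,
                       layer = "R-TF"),
      dplyr::transmute(dec$tft, source = .data$tf, target = .data$target,
                       layer = "TF-target")),
    malignant_subclusters = unique(cfg$cnv_segments$subcluster),
    front_subcluster = {
      fr <- pops$subcluster[pops$zone == "front" & !is.na(pops$subcluster)]
      if (length(fr)) fr else NA_character_
    },
    reference_cells = cells$barcode[cells$compartment == "reference"],
    markers = alloc$markers,
    latent = latent
  )

  structure(list(counts = counts, cells = cells, positions = positions,
                 priors = priors, spatial = spatial, truth = truth,
                 config = cfg),
            class = "synth_bundle")
}

.cascade_edges <- function(cas) {
  purrr::pmap_dfr(cas, function(ligand, receptor, tf, targets, ...) {
    dplyr::bind_rows(
      tibble::tibble(source = ligand, target = receptor, layer = "L-R"),
      tibble::tibble(source = receptor, target = tf, layer = "R-TF"),
      tibble::tibble(source = tf, target = targets, layer = "TF-target"))
  }) |> dplyr::distinct()
}

# Deterministic allocation of planted, decoy and marker genes to the top of
# the gene index range, away from the low-index CNV segments.
.allocate_genes <- function(cfg, genes) {
  n_cascades <- cfg$n_cascades
  tpc <- cfg$targets_per_cascade
  senders <- cfg$populations$name[cfg$populations$compartment == "sender"]
  n_chains <- if (cfg$decoy_priors > 0) {
    max(0, (cfg$decoy_priors - n_cascades) %/% 3)
  } else 0
  n_hang <- if (n_cascades > 0) cfg$decoy_priors - 3 * n_chains else 0
  if (n_cascades == 0) n_chains <- cfg$decoy_priors %/% 3

  need <- n_cascades * (3 + tpc) + n_hang + 4 * n_chains +
    cfg$n_markers * nrow(cfg$populations)
  seg_top <- if (nrow(cfg$cnv_segments)) {
    max(cfg$cnv_segments$first_gene + cfg$cnv_segments$n_genes - 1)
  } else 0
  if (cfg$n_genes - need <= seg_top) {
    abort("n_genes too small for the requested planted structure")
  }
  nxt <- cfg$n_genes - need + 1
  take <- function(k) {
    if (k == 0) return(character())
    out <- genes[seq(nxt, length.out = k)]
    nxt <<- nxt + k
    out
  }
  cascades <- purrr::map_dfr(seq_len(n_cascades), function(i) {
    tibble::tibble(
      name = sprintf("cascade%d", i),
      sender = senders[(i - 1) %% length(senders) + 1],
      receiver = cfg$cascade_receiver,
      ligand = take(1), receptor = take(1), tf = take(1),
      targets = list(take(tpc)))
  })
  if (n_cascades == 0) {
    cascades <- tibble::tibble(name = character(), sender = character(),
                               receiver = character(), ligand = character(),
                               receptor = character(), tf = character(),
                               targets = list())
  }
  hang_targets <- take(n_hang)
  hang <- if (n_hang > 0) {
    tibble::tibble(tf = cascades$tf[(seq_len(n_hang) - 1) %% n_cascades + 1],
                   target = hang_targets)
  } else tibble::tibble(tf = character(), target = character())
  chains <- purrr::map_dfr(seq_len(n_chains), function(i) {
    tibble::tibble(dl = take(1), dr = take(1), df = take(1), dg = take(1))
  })
  if (n_chains == 0) {
    chains <- tibble::tibble(dl = character(), dr = character(),
                             df = character(), dg = character())
  }
  decoys <- list(
    lr = tibble::tibble(ligand = chains$dl, receptor = chains$dr),
    rtf = tibble::tibble(receptor = chains$dr, tf = chains$df),
    tft = dplyr::bind_rows(hang,
                           tibble::tibble(tf = chains$df, target = chains$dg))
  )
  markers <- purrr::map_dfr(cfg$populations$name, function(p) {
    tibble::tibble(population = p, gene = take(cfg$n_markers))
  })
  decoy_genes <- c(hang_targets, chains$dl, chains$dr, chains$df, chains$dg)
  list(cascades = cascades, decoys = decoys, markers = markers,
       decoy_genes = decoy_genes)
}

#' Small packaged fixture bundle
#'
#' A pinned-configuration bundle (200 genes, 400 cells, 2 planted cascades,
#' one CNV-gain subcluster, one front subcluster) used throughout the test
#' suite and documentation. Regenerates byte-identically.
#'
#' @param seed Seed for the pinned configuration (default 42).
#' @return A `synth_bundle`.
#' @export
fixture_small <- function(seed = 42) {
  pops <- tibble::tribble(
    ~name,        ~cell_type,   ~compartment, ~n_cells, ~subcluster, ~zone,    ~group,   ~sample,
    "macrophage", "macrophage", "sender",     100L,     NA,          "immune", "tumor",  "S1",
    "m1",         "epithelial", "receiver",   100L,     "m1",        "core",   "tumor",  "S1",
    "m2",         "epithelial", "receiver",   100L,     "m2",        "front",  "tumor",  "S1",
    "normal epi", "epithelial", "reference",  100L,     NA,          "outer",  "normal", "S0")
  cfg <- synth_config(
    n_genes = 200, n_chromosomes = 4, populations = pops,
    n_cascades = 2, targets_per_cascade = 3, cascade_receiver = "m1",
    effect = 1.5, decoy_priors = 8,
    cnv_segments = tibble::tibble(subcluster = "m1", chrom = 2,
                                  first_gene = 51, n_genes = 40, fold = 1.8),
    n_markers = 4, seed = seed)
  generate_synth(cfg)
}

#' Null configuration: no planted structure
#'
#' Same population scaffold as the defaults but with no cascades, no CNV
#' segments, no markers, a uniform spatial layout, and decoy prior chains
#' only (which carry no signal). Used for null-calibration checks of every
#' screening stage.
#'
#' @param seed Integer seed.
#' @param n_cells_per_population Cells per population (default 80).
#' @param n_genes Gene count (default 300).
#' @param decoy_priors Decoy prior edges, chains only (default 36, i.e. 12
#'   complete chains and 12 L-R pairs).
#' @return A `synth_config`.
#' @export
synth_null_config <- function(seed, n_cells_per_population = 80,
                              n_genes = 300, decoy_priors = 36) {
  pops <- tibble::tribble(
    ~name,        ~cell_type,   ~compartment, ~subcluster, ~zone,    ~group,   ~sample,
    "macrophage", "macrophage", "sender",     NA,          "immune", "tumor",  "S1",
    "m1",         "epithelial", "receiver",   "m1",        "core",   "tumor",  "S1",
    "m2",         "epithelial", "receiver",   "m2",        "front",  "tumor",  "S1",
    "normal epi", "epithelial", "reference",  NA,          "outer",  "normal", "S0")
  pops$n_cells <- as.integer(n_cells_per_population)
  synth_config(
    n_genes = n_genes, n_chromosomes = 6, populations = pops,
    n_cascades = 0, decoy_priors = decoy_priors,
    cnv_segments = tibble::tibble(subcluster = character(), chrom = numeric(),
                                  first_gene = integer(), n_genes = integer(),
                                  fold = numeric()),
    n_markers = 0, spatial = list(layout = "uniform"), seed = seed)
}

#' Write a synthetic bundle to disk in the formats the readers accept
#'
#' Emits the 10x-style triplet matrix, the cell table, gene positions,
#' the three prior tables and the spatial CSV into a directory.
#'
#' @param bundle A `synth_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(bundle$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(gene = rownames(bundle$counts)),
                   file.path(dir, "features.tsv"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(tibble::tibble(barcode = colnames(bundle$counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(bundle$cells, file.path(dir, "cells.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$positions, file.path(dir, "gene_positions.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$priors$lr_pairs, file.path(dir, "priors_lr.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$priors$rtf_links, file.path(dir, "priors_rtf.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$priors$tft_priors, file.path(dir, "priors_tft.tsv"),
                   progress = FALSE)
  readr::write_csv(bundle$spatial, file.path(dir, "spatial.csv"),
                   progress = FALSE)
  invisible(dir)
}
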