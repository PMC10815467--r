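#' Read a gene x cell count matrix
#'
#' Reads raw counts either from a 10x-style MatrixMarket triplet directory
#' (a `.mtx` coordinate file plus gene and barcode text lists) or from a
#' dense TSV whose first column holds gene symbols and whose header row holds
#' cell barcodes. Gene symbols are upper-cased; duplicate symbols are
#' collapsed by summing their rows (the collapse is reported via a message).
#'
#' @param path For `format = "mtx_triplet"`, a directory containing
#'   `matrix.mtx` plus `features.tsv` (or `genes.tsv`) and `barcodes.tsv`;
#'   for `format = "dense_tsv"`, a TSV file.
#' @param format One of `"mtx_triplet"` or `"dense_tsv"`.
#' @return A [`Matrix::dgCMatrix`][Matrix::dgCMatrix-class] of non-negative
#'   integer counts with genes as rows and barcodes as columns.
#' @export
read_counts <- function(path, format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    mtx <- .find_companion(path, c("matrix.mtx"))
    feat <- .find_companion(path, c("features.tsv", "genes.tsv"))
    bcs <- .find_companion(path, c("barcodes.tsv"))
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    genes <- readr::read_tsv(feat, col_names = FALSE, col_types = readr::cols(),
                             progress = FALSE)[[1]]
    barcodes <- readr::read_tsv(bcs, col_names = FALSE, col_types = readr::cols(),
                                progress = FALSE)[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
      abort(sprintf(
        "matrix is %d x %d but gene/barcode lists have %d / %d entries",
        nrow(m), ncol(m), length(genes), length(barcodes)))
    }
    dimnames(m) <- list(genes, barcodes)
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    genes <- as.character(tab[[1]])
    dense <- as.matrix(tab[, -1, drop = FALSE])
    m <- methods::as(Matrix::Matrix(dense, sparse = TRUE), "CsparseMatrix")
    dimnames(m) <- list(genes, colnames(tab)[-1])
  }
  validate_counts(.collapse_duplicate_genes(.harmonize_rownames(m)))
}

.find_companion <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  abort(sprintf("missing companion file in %s: expected one of %s",
                dir, paste(candidates, collapse = ", ")))
}

.harmonize_rownames <- function(m) {
  rownames(m) <- toupper(rownames(m))
  m
}

.collapse_duplicate_genes <- function(m) {
  g <- rownames(m)
  if (anyDuplicated(g)) {
    dup <- unique(g[duplicated(g)])
    inform(sprintf("collapsed %d duplicated gene symbol(s) by summing rows: %s",
                   length(dup), paste(head(dup, 5), collapse = ", ")))
    f <- factor(g, levels = unique(g))
    m <- Matrix::fac2sparse(f) %*% m
    m <- methods::as(m, "CsparseMatrix")
  }
  m
}

#' Validate a count matrix
#'
#' Checks the count-matrix contract: unique gene symbols and barcodes,
#' non-negative integer entries, consistent dimnames.
#'
#' @param m A genes x cells sparse matrix.
#' @return `m`, invisibly cast to `dgCMatrix`, if valid; otherwise an error.
#' @export
validate_counts <- function(m) {
  m <- methods::as(m, "CsparseMatrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("count matrix must carry gene rownames and barcode colnames")
  }
  if (anyDuplicated(rownames(m))) abort("duplicate gene symbols")
  if (anyDuplicated(colnames(m))) abort("duplicate cell barcodes")
  x <- m@x
  if (length(x) && any(x < 0)) abort("negative entries in count matrix")
  if (length(x) && any(abs(x - round(x)) > 1e-8)) {
    abort("non-integer entries in count matrix")
  }
  m
}

#' Read prior-knowledge edge tables
#'
#' Loads the three layers of the multilayer scaffold: ligand-receptor pairs,
#' receptor-TF links, and TF-target motif priors. Symbols are upper-cased
#' and duplicates removed; TF-target self-loops are dropped with a warning.
#'
#' @param lr_path TSV with columns `ligand`, `receptor`.
#' @param rtf_path TSV with columns `receptor`, `tf` and optionally `pathway`.
#' @param tft_path TSV with columns `tf`, `target` and optionally `motif`
#'   (logical motif-evidence flag; missing column means all `TRUE`).
#' @return A `prior_knowledge` object: a list of tibbles `lr_pairs`,
#'   `rtf_links`, `tft_priors`.
#' @export
read_priors <- function(lr_path, rtf_path, tft_path) {
  lr <- .read_prior_table(lr_path, c("ligand", "receptor"))
  rtf <- .read_prior_table(rtf_path, c("receptor", "tf"), optional = "pathway")
  tft <- .read_prior_table(tft_path, c("tf", "target"), optional = "motif")
  prior_knowledge(lr, rtf, tft)
}

.read_prior_table <- function(path, required, optional = character()) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s) %s",
                  path, paste(missing, collapse = ", ")))
  }
  if (nrow(tab) == 0) warn(sprintf("%s: empty prior table", path))
  tab[, intersect(c(required, optional), names(tab)), drop = FALSE]
}

#' Construct a prior-knowledge object from in-memory tables
#'
#' @param lr_pairs Data frame with columns `ligand`, `receptor`.
#' @param rtf_links Data frame with columns `receptor`, `tf`.
#' @param tft_priors Data frame with columns `tf`, `target` and optional
#'   logical `motif`.
#' @return A `prior_knowledge` object.
#' @export
prior_knowledge <- function(lr_pairs, rtf_links, tft_priors) {
  up <- function(tab, cols) {
    for (cl in cols) tab[[cl]] <- toupper(as.character(tab[[cl]]))
    dplyr::distinct(tibble::as_tibble(tab))
  }
  lr <- up(lr_pairs, c("ligand", "receptor"))
  rtf <- up(rtf_links, c("receptor", "tf"))
  tft <- up(tft_priors, c("tf", "target"))
  if (!"motif" %in% names(tft)) tft$motif <- TRUE
  loops <- tft$tf == tft$target
  if (any(loops)) {
    warn(sprintf("dropped %d TF-target self-loop(s): %s", sum(loops),
                 paste(head(unique(tft$tf[loops]), 5), collapse = ", ")))
    tft <- tft[!loops, , drop = FALSE]
  }
  out <- list(lr_pairs = lr, rtf_links = rtf, tft_priors = tft)
  structure(out, class = "prior_knowledge")
}

#' @export
print.prior_knowledge <- function(x, ...) {
  cat(sprintf("<prior_knowledge> %d L-R pairs, %d R-TF links, %d TF-target priors\n",
              nrow(x$lr_pairs), nrow(x$rtf_links), nrow(x$tft_priors)))
  invisible(x)
}

#' Read a gene genomic-position table
#'
#' TSV with columns `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' Chromosome sort order is the order of first appearance in the file, not
#' alphabetic, so `chr10` never sorts before `chr2` by accident.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `chrom` as a factor carrying the declared order.
#' @export
read_gene_positions <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  missing <- setdiff(c("gene", "chrom", "start", "end"), names(tab))
  if (length(missing)) {
    abort(sprintf("gene position file missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  validate_gene_positions(tab)
}

#' Validate a gene-position table
#'
#' @param tab Data frame with columns `gene`, `chrom`, `start`, `end`.
#' @return A validated tibble; `chrom` becomes a factor in first-appearance
#'   order if it is not already a factor.
#' @export
validate_gene_positions <- function(tab) {
  tab <- tibble::as_tibble(tab)
  tab$gene <- toupper(as.character(tab$gene))
  if (anyDuplicated(tab$gene)) abort("duplicate genes in position table")
  if (any(tab$start > tab$end)) abort("gene position with start > end")
  if (!is.factor(tab$chrom)) {
    tab$chrom <- factor(tab$chrom, levels = unique(as.character(tab$chrom)))
  }
  tab
}

#' Read spatial coordinates
#'
#' CSV with columns `unit_id`, `x`, `y` and optionally `label`.
#'
#' @param path Path to the CSV file.
#' @return A tibble of unique units with finite planar coordinates.
#' @export
read_spatial <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  missing <- setdiff(c("unit_id", "x", "y"), names(tab))
  if (length(missing)) {
    abort(sprintf("spatial file missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tab$unit_id)) abort("duplicate unit_id in spatial table")
  if (!all(is.finite(tab$x)) || !all(is.finite(tab$y))) {
    abort("non-finite spatial coordinates")
  }
  tibble::as_tibble(tab)
}

#' Write an intercellular network to disk
#'
#' `edge_tsv` writes exactly the columns
#' `source, target, layer, sender_population, receiver_population, score`;
#' `json` writes a single object with node and edge arrays plus the sender,
#' receiver and stage fields. `read_igrn()` round-trips both formats.
#'
#' @param network An `igrn` object.
#' @param path Output file path.
#' @param format `"edge_tsv"` or `"json"`.
#' @return `network`, invisibly.
#' @export
write_igrn <- function(network, path, format = c("edge_tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "igrn"))
  if (format == "edge_tsv") {
    edges <- network$edges |>
      dplyr::mutate(sender_population = network$sender,
                    receiver_population = network$receiver) |>
      dplyr::select("source", "target", "layer",
                    "sender_population", "receiver_population", "score")
    readr::write_tsv(edges, path, progress = FALSE)
  } else {
    obj <- list(
      sender = network$sender,
      receiver = network$receiver,
      stage = network$stage,
      nodes = network$nodes,
      edges = network$edges
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(network)
}

#' Read an intercellular network written by [write_igrn()]
#'
#' @param path File path.
#' @param format `"edge_tsv"` or `"json"`.
#' @param sender,receiver Population labels; required for `edge_tsv` input
#'   only when the file has no rows (an empty network carries no
#'   population columns to recover them from).
#' @param stage Network stage for `edge_tsv` input (the TSV does not store
#'   it); default `"pruned"`.
#' @return An `igrn` object.
#' @export
read_igrn <- function(path, format = c("edge_tsv", "json"),
                      sender = NULL, receiver = NULL, stage = "pruned") {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- tibble::as_tibble(obj$nodes)
    edges <- tibble::as_tibble(obj$edges)
    if (nrow(edges) == 0) {
      edges <- tibble::tibble(source = character(), target = character(),
                              layer = character(), score = numeric())
    }
    if (nrow(nodes) == 0) {
      nodes <- tibble::tibble(gene = character(), role = character())
    }
    return(new_igrn(nodes, edges, obj$sender, obj$receiver, obj$stage,
                    validate = FALSE))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (nrow(tab)) {
    sender <- sender %||% tab$sender_population[1]
    receiver <- receiver %||% tab$receiver_population[1]
  }
  edges <- tibble::tibble(source = as.character(tab$source),
                          target = as.character(tab$target),
                          layer = as.character(tab$layer),
                          score = as.numeric(tab$score))
  nodes <- .nodes_from_edges(edges)
  new_igrn(nodes, edges, sender %||% NA_character_,
           receiver %||% NA_character_, stage, validate = FALSE)
}

.nodes_from_edges <- function(edges) {
  role_of <- c("L-R" = "ligand", "R-TF" = "receptor", "TF-target" = "tf")
  target_role <- c("L-R" = "receptor", "R-TF" = "tf", "TF-target" = "target")
  nodes <- dplyr::bind_rows(
    tibble::tibble(gene = edges$source, role = unname(role_of[edges$layer])),
    tibble::tibble(gene = edges$target, role = unname(target_role[edges$layer]))
  )
  dplyr::distinct(nodes) |> dplyr::arrange(.data$gene, .data$role)
}
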