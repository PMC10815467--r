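# Independent brute-force oracles. Each is written as a plain loop against
# the mathematical definition and must stay independent of the package
# implementation it checks.

# Exact two-sided rank-sum p by full enumeration of the choose(n, nx) rank
# assignments. Assumes no ties.
oracle_ranksum_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  center <- nx * ny / 2
  combos <- utils::combn(nx + ny, nx)
  all_ranks <- seq_len(nx + ny)
  w_perm <- apply(combos, 2, function(idx) sum(all_ranks[idx])) -
    nx * (nx + 1) / 2
  mean(abs(w_perm - center) >= abs(w_obs - center) - 1e-12)
}

# Recovery-curve AUC by explicit stepwise integration.
oracle_aucell <- function(values, genes, targets, top_fraction) {
  stopifnot(length(values) == length(genes))
  ord <- order(-values, genes)
  ranked <- genes[ord]
  w <- ceiling(top_fraction * length(genes))
  hits <- 0
  area <- 0
  for (i in seq_len(w)) {
    if (ranked[i] %in% targets) hits <- hits + 1
    area <- area + hits
  }
  k <- min(length(intersect(targets, genes)), w)
  max_area <- 0
  best <- 0
  for (i in seq_len(w)) {
    if (best < k) best <- best + 1
    max_area <- max_area + best
  }
  area / max_area
}

# Mean distance to the k nearest reference points, all pairs by loop.
oracle_kdist <- function(qx, qy, rx, ry, k) {
  out <- numeric(length(qx))
  for (i in seq_along(qx)) {
    d <- sqrt((qx[i] - rx)^2 + (qy[i] - ry)^2)
    out[i] <- mean(sort(d)[seq_len(k)])
  }
  out
}

# Full CNV residual pipeline re-implemented with scalar loops.
oracle_cnv_residuals <- function(counts, chrom, ref_idx, window,
                                 scale_factor = 1e4) {
  totals <- colSums(counts)
  norm <- counts
  for (j in seq_len(ncol(counts))) {
    fac <- if (totals[j] > 0) scale_factor / totals[j] else 0
    norm[, j] <- log1p(counts[, j] * fac)
  }
  x <- t(norm)                                  # cells x genes
  for (g in seq_len(ncol(x))) {
    x[, g] <- x[, g] - mean(x[ref_idx, g])
  }
  x[x > 3] <- 3; x[x < -3] <- -3
  h <- (window - 1) / 2
  sm <- x
  for (g in seq_len(ncol(x))) {
    same <- which(chrom == chrom[g])
    win <- same[same >= g - h & same <= g + h]
    for (cl in seq_len(nrow(x))) sm[cl, g] <- mean(x[cl, win])
  }
  for (cl in seq_len(nrow(sm))) sm[cl, ] <- sm[cl, ] - median(sm[cl, ])
  for (g in seq_len(ncol(sm))) sm[, g] <- sm[, g] - mean(sm[ref_idx, g])
  sm
}
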