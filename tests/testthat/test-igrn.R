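# Tiny expression setting around the published example chain:
# AREG (macrophage ligand) -> ERBB3 -> FOXA1 -> ESR1 in the receiver.
areg_world <- function(n = 40) {
  genes <- c("AREG", "ERBB3", "FOXA1", "ESR1", "OTHER")
  senders <- sprintf("mac%02d", seq_len(n))
  receivers <- sprintf("mal%02d", seq_len(n))
  m <- matrix(0, length(genes), 2 * n,
              dimnames = list(genes, c(senders, receivers)))
  m["AREG", senders] <- 3
  m["ERBB3", receivers] <- 2
  m["FOXA1", receivers] <- 2
  m["ESR1", receivers] <- 2
  m["OTHER", ] <- 1
  cells <- tibble::tibble(
    barcode = c(senders, receivers),
    cell_type = rep(c("macrophage", "epithelial"), each = n),
    subcluster = rep(c(NA, "m_cluster2"), each = n))
  list(m = m, cells = cells, genes = genes)
}

test_that("permutation L-R scoring gates, scores and floors correctly", {
  w <- areg_world()
  pk <- areg_chain_priors()
  lr <- lr_score(w$m, w$cells, "macrophage", "m_cluster2", pk,
                 n_perm = 999, seed = 2)
  expect_identical(nrow(lr), 1L)
  expect_equal(lr$score, (3 + 2) / 2)
  expect_equal(lr$p_value, 1 / 1000)     # permutation floor
  expect_gte(lr$p_value, 1 / 1000)

  # identical seeds reproduce; different seeds keep the same observed score
  lr2 <- lr_score(w$m, w$cells, "macrophage", "m_cluster2", pk,
                  n_perm = 999, seed = 2)
  expect_identical(lr, lr2)
  lr3 <- lr_score(w$m, w$cells, "macrophage", "m_cluster2", pk,
                  n_perm = 99, seed = 77)
  expect_equal(lr3$score, lr$score)

  # an all-zero pair is gated out
  w0 <- w
  w0$m["AREG", ] <- 0
  expect_warning(
    out <- lr_score(w0$m, w0$cells, "macrophage", "m_cluster2", pk,
                    n_perm = 99, seed = 1),
    "expression gate")
  expect_identical(nrow(out), 0L)
})

test_that("the example chain assembles into a 4-node, 3-edge network", {
  w <- areg_world()
  pk <- areg_chain_priors()
  lr <- lr_score(w$m, w$cells, "macrophage", "m_cluster2", pk,
                 n_perm = 999, seed = 2)
  net <- build_preliminary(w$m, w$cells, "macrophage", "m_cluster2", pk, lr)
  expect_identical(nrow(net$nodes), 4L)
  expect_identical(nrow(net$edges), 3L)
  expect_identical(net$edges$layer, c("L-R", "R-TF", "TF-target"))
  expect_identical(net$stage, "preliminary")

  paths <- extract_paths(net)
  expect_identical(nrow(paths), 1L)
  expect_identical(unlist(paths[1, ], use.names = FALSE),
                   c("AREG", "ERBB3", "FOXA1", "ESR1"))
  expect_identical(count_signals(net),
                   tibble::tibble(lr = 1L, rtf = 1L, tf_target = 1L,
                                  total = 3L))
})

test_that("an unexpressed receptor removes its whole downstream branch", {
  w <- areg_world()
  w$m["ERBB3", ] <- 0
  pk <- areg_chain_priors()
  lr <- suppressWarnings(
    lr_score(w$m, w$cells, "macrophage", "m_cluster2", pk,
             n_perm = 99, seed = 1))
  net <- suppressMessages(
    build_preliminary(w$m, w$cells, "macrophage", "m_cluster2", pk, lr))
  expect_identical(nrow(net$edges), 0L)
  expect_identical(nrow(net$nodes), 0L)
  expect_identical(nrow(extract_paths(net)), 0L)
  expect_identical(count_signals(net)$total, 0L)

  empty_lr <- lr[0, ]
  net2 <- suppressMessages(
    build_preliminary(w$m, w$cells, "macrophage", "m_cluster2", pk,
                      empty_lr))
  expect_identical(nrow(net2$edges), 0L)
})

test_that("pruning keeps exactly the regulon-and-DEG intersection", {
  edges <- tibble::tibble(
    source = c("L", "R", "F1", "F1", "F2", "R"),
    target = c("R", "F1", "g1", "g2", "g3", "F2"),
    layer = c("L-R", "R-TF", "TF-target", "TF-target", "TF-target", "R-TF"),
    score = c(1, NA, NA, NA, NA, NA))
  net <- new_igrn(NULL, edges, "s", "r", "preliminary", validate = TRUE)
  expect_identical(nrow(net$edges), 6L)

  regulons <- tibble::tibble(tf = "F1", target = "g1", score = 0.9)
  degs <- tibble::tibble(gene = c("g1", "g3"))
  pruned <- prune_igrn(net, regulons, degs)
  expect_identical(pruned$stage, "pruned")
  expect_identical(nrow(pruned$edges), 3L)
  tft <- pruned$edges[pruned$edges$layer == "TF-target", ]
  expect_identical(paste(tft$source, tft$target), "F1 g1")
  # subset invariant
  expect_true(all(paste(pruned$edges$source, pruned$edges$target) %in%
                    paste(net$edges$source, net$edges$target)))

  # no active regulons -> nothing survives validation
  none <- prune_igrn(net, regulons[0, ], degs)
  expect_identical(nrow(none$edges), 0L)
  expect_false(any(c("tf", "target") %in% none$nodes$role))
})

test_that("path extraction enumerates layer-respecting simple paths", {
  diamond <- tibble::tibble(
    source = c("L", "R", "R", "F1", "F2"),
    target = c("R", "F1", "F2", "g1", "g2"),
    layer = c("L-R", "R-TF", "R-TF", "TF-target", "TF-target"),
    score = NA_real_)
  net <- new_igrn(NULL, diamond, "s", "r", "preliminary")
  paths <- extract_paths(net)
  expect_identical(nrow(paths), 2L)
  expect_identical(paths$tf, c("F1", "F2"))
  # lexicographic determinism
  expect_identical(paths, paths[order(paths$ligand, paths$receptor,
                                      paths$tf, paths$target), ])
})

test_that("network validation enforces role/layer consistency", {
  bad <- tibble::tibble(source = "A", target = "B", layer = "X-Y",
                        score = NA_real_)
  expect_error(new_igrn(NULL, bad, "s", "r", "preliminary"), "unknown edge")
})
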