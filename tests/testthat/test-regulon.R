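test_that("co-expression scoring is |Spearman| with self-pairs excluded", {
  set.seed(19)
  n <- 500
  tfv <- rnorm(n)
  m <- rbind(TF1 = tfv, COPY = tfv, ANTI = -tfv, NOISE = rnorm(n),
             FLAT = rep(1, n))
  colnames(m) <- sprintf("c%03d", seq_len(n))
  sc <- coexpression_scores(m, tfs = "TF1",
                            candidate_targets = rownames(m), min_score = 0)
  expect_equal(sc$score[sc$target == "COPY"], 1)
  expect_equal(sc$score[sc$target == "ANTI"], 1)    # absolute value
  expect_equal(sc$score[sc$target == "FLAT"], 0)
  expect_false("TF1" %in% sc$target)                # self-pair gone
  expect_lt(sc$score[sc$target == "NOISE"], 0.1)

  gated <- coexpression_scores(m, "TF1", rownames(m), min_score = 0.1)
  expect_setequal(gated$target, c("COPY", "ANTI"))
})

test_that("motif pruning is a set intersection grouped by TF", {
  scored <- tibble::tibble(tf = c("F1", "F1", "F2"),
                           target = c("g1", "g2", "g3"),
                           score = c(0.9, 0.8, 0.7))
  pk <- prior_knowledge(
    data.frame(ligand = "L", receptor = "R"),
    data.frame(receptor = "R", tf = "F1"),
    data.frame(tf = c("F1", "F2", "F9"), target = c("G1", "G3", "G9"),
               motif = c(TRUE, FALSE, TRUE)))
  reg <- prune_by_motif(dplyr::mutate(scored, tf = toupper(tf),
                                      target = toupper(target)), pk)
  expect_identical(nrow(reg), 1L)                   # F2-G3 lacks motif support
  expect_identical(reg$tf, "F1")
  expect_identical(reg$target, "G1")

  empty_pk <- prior_knowledge(
    data.frame(ligand = "L", receptor = "R"),
    data.frame(receptor = "R", tf = "F1"),
    data.frame(tf = character(), target = character()))
  expect_identical(nrow(prune_by_motif(scored, empty_pk)), 0L)
  # output is a subset of scored pairs intersected with priors
  expect_true(all(paste(reg$tf, reg$target) %in%
                    paste(toupper(scored$tf), toupper(scored$target))))
})

test_that("recovery-curve AUC matches brute-force integration", {
  # 10 genes, window 5, targets at ranks 1 and 4
  vals <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  genes <- sprintf("g%02d", 1:10)
  m <- matrix(vals, ncol = 1, dimnames = list(genes, "cell1"))
  reg <- tibble::tibble(tf = "TF", target = c("g01", "g04"))
  out <- aucell_activity(m, reg, top_fraction = 0.5)
  expect_equal(out$auc, (1 + 1 + 1 + 2 + 2) / (1 + 2 + 2 + 2 + 2))
  expect_equal(out$auc, oracle_aucell(vals, genes, reg$target, 0.5))

  # maximal and empty recovery
  top <- tibble::tibble(tf = "TF", target = c("g01", "g02"))
  expect_equal(aucell_activity(m, top, 0.5)$auc, 1)
  bottom <- tibble::tibble(tf = "TF", target = c("g09", "g10"))
  expect_equal(aucell_activity(m, bottom, 0.2)$auc, 0)

  set.seed(41)
  for (rep in 1:30) {
    n_genes <- sample(4:12, 1)
    genes <- sprintf("g%02d", seq_len(n_genes))
    vals <- sample(50, n_genes)           # distinct: rank ties exercised below
    targets <- sample(genes, sample(seq_len(n_genes - 1), 1))
    frac <- runif(1, 0.1, 1)
    m <- matrix(vals, ncol = 1, dimnames = list(genes, "c"))
    got <- aucell_activity(m, tibble::tibble(tf = "T", target = targets),
                           frac)$auc
    expect_lt(abs(got - oracle_aucell(vals, genes, targets, frac)), 1e-12)
  }
  # expression ties broken lexicographically: oracle uses the same rule
  vals <- c(5, 5, 5, 1)
  genes <- c("gd", "gb", "ga", "gc")
  m <- matrix(vals, ncol = 1, dimnames = list(genes, "c"))
  tg <- tibble::tibble(tf = "T", target = "ga")
  expect_equal(aucell_activity(m, tg, 0.5)$auc,
               oracle_aucell(vals, genes, "ga", 0.5))
})

test_that("AUC is invariant to rank-preserving rescaling", {
  set.seed(55)
  m <- matrix(rexp(20 * 6), 20, 6,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%d", 1:6)))
  reg <- tibble::tibble(tf = "T", target = c("g03", "g11", "g17"))
  a1 <- aucell_activity(m, reg, 0.25)
  a2 <- aucell_activity(log1p(m) * 7, reg, 0.25)
  expect_equal(a1, a2)
  expect_true(all(a1$auc >= 0 & a1$auc <= 1))
  expect_error(
    aucell_activity(m, tibble::tibble(tf = "T", target = "NOPE"), 0.25),
    "no targets")
})

test_that("active-TF calling uses the mean + 2sd threshold per regulon", {
  cells <- sprintf("c%03d", 1:100)
  recv <- cells[1:40]
  act <- dplyr::bind_rows(
    tibble::tibble(tf = "DEAD", cell = cells, auc = 0),
    tibble::tibble(tf = "HOT", cell = cells,
                   auc = c(rep(0.9, 15), rep(0.01, 85))),
    tibble::tibble(tf = "COLD", cell = cells,
                   auc = c(rep(0.01, 60), rep(0.9, 15), rep(0.01, 25))))
  res <- active_tfs(act, recv)
  expect_false(res$is_active[res$tf == "DEAD"])
  expect_true(res$is_active[res$tf == "HOT"])    # 15/40 receiver cells high
  expect_false(res$is_active[res$tf == "COLD"])  # high cells are non-receiver
  # boundary: every receiver cell must exceed the threshold
  strict <- active_tfs(act, recv, min_fraction_active = 1)
  expect_false(any(strict$is_active))
})

test_that("planted regulons are recovered and shuffled decoys are not", {
  b <- the_fixture()
  norm <- normalize_counts(b$counts)
  recv <- b$cells$barcode[!is.na(b$cells$subcluster) &
                            b$cells$subcluster == "m1"]
  sc <- coexpression_scores(norm[, recv], unique(b$priors$tft_priors$tf),
                            unique(b$priors$tft_priors$target))
  reg <- prune_by_motif(sc, b$priors)
  act <- aucell_activity(norm, reg, 0.05)
  res <- active_tfs(act, recv)
  planted <- b$truth$cascades$tf
  decoy_tfs <- setdiff(unique(b$priors$tft_priors$tf), planted)
  expect_true(all(planted %in% res$tf[res$is_active]))
  expect_false(any(decoy_tfs %in% res$tf[res$is_active]))
})
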