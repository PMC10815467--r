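sp_tab <- function(x, y, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("u%03d", seq_along(x))
  tibble::tibble(unit_id = ids, x = x, y = y)
}

test_that("kdist reproduces hand-computed and brute-force distances", {
  q <- sp_tab(0, 0, "q")
  r <- sp_tab(c(0, 3, 6), c(1, 4, 8))
  expect_equal(kdist(q, r, k = 2)$kdist, 3.0)          # mean of 1 and 5
  expect_equal(kdist(q, r, k = 3)$kdist, mean(c(1, 5, 10)))
  expect_equal(kdist(r, r, k = 1)$kdist, c(0, 0, 0))
  expect_warning(kd <- kdist(q, r, k = 10), "truncated")
  expect_identical(kd$k, 3L)

  set.seed(14)
  q2 <- sp_tab(runif(40, -5, 5), runif(40, -5, 5))
  r2 <- sp_tab(runif(60, -5, 5), runif(60, -5, 5))
  for (k in c(1, 5, 60)) {
    expect_lt(max(abs(kdist(q2, r2, k)$kdist -
                        oracle_kdist(q2$x, q2$y, r2$x, r2$y, k))), 1e-12)
  }
  # kdist never decreases in k
  k1 <- kdist(q2, r2, 3)$kdist; k2 <- kdist(q2, r2, 10)$kdist
  expect_true(all(k2 >= k1 - 1e-12))
})

test_that("kdist is invariant under rigid motions", {
  set.seed(3)
  q <- sp_tab(rnorm(25), rnorm(25))
  r <- sp_tab(rnorm(35), rnorm(35))
  base <- kdist(q, r, 4)$kdist
  th <- 0.7; rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  mv <- function(tab) {
    xy <- as.matrix(tab[, c("x", "y")]) %*% rot
    sp_tab(xy[, 1] + 11, xy[, 2] - 4, tab$unit_id)
  }
  expect_equal(kdist(mv(q), mv(r), 4)$kdist, base, tolerance = 1e-10)
})

test_that("spot composition scores separate planted cell types", {
  b <- the_fixture()
  markers <- split(b$truth$markers$gene, b$truth$markers$population)
  sc <- score_spot_composition(b$counts, b$spatial, markers)
  zone <- setNames(b$cells$zone, b$cells$barcode)
  mal <- sc[sc$cell_type == "m1", ]
  expect_gt(mean(mal$score[zone[mal$unit_id] == "core"]),
            mean(mal$score[zone[mal$unit_id] == "immune"]))
  mac <- sc[sc$cell_type == "macrophage", ]
  expect_gt(mean(mac$score[zone[mac$unit_id] == "immune"]),
            mean(mac$score[zone[mac$unit_id] == "core"]))

  flat <- make_counts(matrix(3, 4, 5))
  sp <- sp_tab(1:5, 1:5, colnames(flat))
  zs <- score_spot_composition(flat, sp, list(t = rownames(flat)[1:2]))
  expect_true(all(zs$score == 0))
  expect_error(score_spot_composition(flat, sp, list(t = "NOPE")),
               "no marker genes")
})

test_that("front calls flag the annulus subcluster and only it", {
  b <- the_fixture()
  sub_of <- setNames(b$cells$subcluster, b$cells$barcode)
  mal <- dplyr::mutate(b$spatial, subcluster = unname(sub_of[unit_id])) |>
    dplyr::filter(!is.na(subcluster))
  imm <- dplyr::filter(b$spatial, label == "macrophage")
  calls <- call_front(mal, imm)
  expect_identical(calls$subcluster[which(calls$is_front)], "m2")
  expect_false(calls$is_front[calls$subcluster == "m1"])

  none <- call_front(mal, imm, alpha = 0)
  expect_false(any(none$is_front))

  # relabeling leaves the geometry, hence the calls, unchanged
  relabeled <- dplyr::mutate(mal, subcluster = paste0("X", subcluster))
  calls2 <- call_front(relabeled, imm)
  expect_identical(calls2$is_front,
                   calls$is_front[match(sub("^X", "", calls2$subcluster),
                                        calls$subcluster)])
})

test_that("degenerate front inputs are handled explicitly", {
  set.seed(9)
  pts <- sp_tab(runif(40), runif(40))
  # identical spatial distributions: duplicate coordinates, two labels
  both <- dplyr::bind_rows(
    dplyr::mutate(pts, subcluster = "a"),
    dplyr::mutate(pts, unit_id = paste0(unit_id, "b"), subcluster = "b"))
  imm <- sp_tab(runif(30), runif(30), sprintf("i%02d", 1:30))
  calls <- call_front(both, imm, k = 5)
  expect_false(any(calls$is_front))

  single <- dplyr::mutate(pts, subcluster = "only")
  expect_message(one <- call_front(single, imm), "undefined")
  expect_true(all(is.na(one$is_front)))
  expect_error(call_front(dplyr::mutate(pts, label = NULL), imm), "subcluster")
})
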