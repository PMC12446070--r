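test_that("per-gene correlation matches stats::cor and flags constants", {
  set.seed(1)
  p <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("g", 1:4)))
  t <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("g", 1:4)))
  t[, 3] <- 5                       # constant truth
  got <- per_gene_pcc(p, t)
  expect_equal(got$pcc[1], cor(p[, 1], t[, 1]))
  expect_true(is.na(got$pcc[3]))
  expect_error(per_gene_pcc(p[1, , drop = FALSE], t[1, , drop = FALSE]),
               "at least 2 cells")
})

test_that("SSIM is 1 for identical images and decreases under distortion", {
  set.seed(2)
  x <- matrix(runif(32 * 32, 0, 10), 32, 32)
  expect_equal(ssim(x, x, dynamic_range = 10), 1, tolerance = 1e-9)
  y <- x + matrix(rnorm(1024, 0, 2), 32, 32)
  s <- ssim(x, y, dynamic_range = 10)
  expect_lt(s, 1)
  expect_gt(s, -1)
  expect_error(ssim(x[1:5, 1:5], x[1:5, 1:5], 10), "window")
})

test_that("expression rasterization sums counts per grid bin", {
  v <- matrix(c(1, 2, 4), 3, 1, dimnames = list(NULL, "g1"))
  # two cells in the same corner bin, one in the opposite corner
  r <- rasterize_expression(v, rows = c(1, 2, 63), cols = c(1, 2, 63),
                            extent = c(64, 64), grid = 4L)
  expect_equal(unname(r[1, 1, 1]), 3)
  expect_equal(unname(r[4, 4, 1]), 4)
  expect_equal(sum(r), 7)
})

test_that("per-gene SSIM flags zero-range truth and scores structure", {
  set.seed(3)
  n <- 200
  rows <- runif(n, 1, 64); cols <- runif(n, 1, 64)
  truth <- cbind(g1 = as.numeric(rows > 32) * 5 + 1, g2 = rep(0, n))
  pred_close <- truth + matrix(abs(rnorm(2 * n, 0, 0.2)), n, 2)
  pred_flat <- matrix(3, n, 2, dimnames = list(NULL, c("g1", "g2")))
  s1 <- ssim_per_gene(pred_close, truth, rows, cols, extent = c(64, 64), grid = 16L)
  s2 <- ssim_per_gene(pred_flat, truth, rows, cols, extent = c(64, 64), grid = 16L)
  expect_true(is.na(s1$ssim[2]))     # constant truth gene
  expect_gt(s1$ssim[1], s2$ssim[1])
})

test_that("cell-type metrics match hand counts and handle label mismatch", {
  pred <- c("a", "a", "b", "b", "c")
  truth <- c("a", "b", "b", "b", "a")
  got <- celltype_metrics(pred, truth)
  expect_equal(got$accuracy, 3 / 5)
  # class a: tp 1, pred 2, true 2 -> f1 = 2*1/(2+2) = 0.5
  expect_equal(unname(got$f1["a"]), 0.5)
  # class c: never true -> denominator pred only
  expect_equal(unname(got$f1["c"]), 0)
  expect_equal(got$macro_f1, mean(got$f1))
  expect_equal(sum(got$composition_pred), 1)
  # extra levels appear with zero counts
  got2 <- celltype_metrics(pred, truth, levels = c("a", "b", "c", "d"))
  expect_equal(unname(got2$f1["d"]), 0)
  expect_length(got2$composition_true, 4L)
  expect_error(celltype_metrics(c("a", "z"), c("a", "a"), levels = c("a", "b")),
               "outside")
})

test_that("variable-gene ranking uses variance of log values and checks k", {
  v <- matrix(1, 10, 3, dimnames = list(NULL, c("flat", "var1", "var2")))
  v[, 2] <- rep(c(0, 20), 5)
  v[, 3] <- rep(c(0, 5), 5)
  e <- expression_matrix(v, scale = "raw_counts")
  expect_identical(top_variable_genes(e, 2L), c("var1", "var2"))
  expect_error(top_variable_genes(e, 4L), "exceeds")
})

test_that("stratified correlation summarizes gene sets and rejects unknown genes", {
  pg <- tibble::tibble(gene = paste0("g", 1:6),
                       pcc = c(0.9, 0.8, 0.2, 0.1, NA, 0.5))
  out <- stratified_correlation(pg, list(hv = c("g1", "g2"), rest = c("g3", "g4", "g5")))
  expect_equal(out$median[out$set == "hv"], 0.85)
  expect_identical(out$n[out$set == "rest"], 2L)  # NA excluded
  expect_error(stratified_correlation(pg, list(bad = "nope")), "absent")
})

test_that("spot rollup averages images within individuals before genes", {
  per_image <- tibble::tibble(
    image = c("i1", "i2", "i3", "i1", "i2", "i3"),
    gene = rep(c("g1", "g2"), each = 3),
    pcc = c(0.2, 0.4, 0.9, 0.0, 0.2, 0.7))
  indiv <- c(i1 = "A", i2 = "A", i3 = "B")
  out <- spot_metric_rollup(per_image, indiv)
  # g1: A = mean(0.2, 0.4) = 0.3, B = 0.9 -> 0.6
  expect_equal(out$value[out$gene == "g1"], 0.6)
  expect_equal(out$value[out$gene == "g2"], mean(c(0.1, 0.7)))
  expect_error(spot_metric_rollup(per_image, c(i1 = "A")), "without an individual")
})

test_that("gene scatter plot builds from expression matrices", {
  e1 <- expression_matrix(matrix(abs(rnorm(20)), 10, 2,
                                 dimnames = list(NULL, c("g1", "g2"))),
                          scale = "log_normalized")
  e2 <- expression_matrix(matrix(abs(rnorm(20)), 10, 2,
                                 dimnames = list(NULL, c("g1", "g2"))),
                          scale = "log_normalized")
  pl <- plot_gene_scatter(e1, e2, "g1")
  expect_s3_class(pl, "ggplot")
})
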