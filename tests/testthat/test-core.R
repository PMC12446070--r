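test_that("he_patch validates shape and intensity range", {
  expect_s3_class(he_patch(array(0, c(4, 4, 3)), mpp = 0.5), "he_patch")
  expect_error(he_patch(array(0, c(4, 4, 2)), mpp = 0.5))
  expect_error(he_patch(array(-1, c(4, 4, 3)), mpp = 0.5), "intensities")
  expect_error(he_patch(array(256, c(4, 4, 3)), mpp = 0.5), "intensities")
})

test_that("instance_map derives and validates ids", {
  lab <- matrix(0L, 4, 4); lab[1:2, 1:2] <- 3L; lab[4, 4] <- 9L
  m <- instance_map(lab)
  expect_identical(m$valid_ids, c(3L, 9L))
  expect_identical(instance_map(lab, valid_ids = 9L)$valid_ids, 9L)
  expect_error(instance_map(lab, valid_ids = 5L), "valid_ids")
  expect_error(instance_map(matrix(-1L, 2, 2)), "non-negative")
})

test_that("cell_table enforces id uniqueness and derives area_um2", {
  df <- data.frame(id = 1:2, centroid_row = c(1, 2), centroid_col = c(1, 2),
                   area_px = c(4, 8))
  ct <- cell_table(df, mpp = 0.5)
  expect_equal(ct$area_um2, c(1, 2))
  expect_error(cell_table(df[c(1, 1), ], mpp = 0.5), "unique")
  # duplicate ids in different patches are fine
  df2 <- cbind(df[c(1, 1), ], patch = 1:2)
  expect_s3_class(cell_table(df2, mpp = 0.5), "cell_table")
  expect_error(cell_table(df[, -1], mpp = 0.5), "missing columns")
})

test_that("expression_matrix and reference_profiles validate inputs", {
  v <- matrix(1:6, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  e <- expression_matrix(v, scale = "raw_counts")
  expect_identical(dim(e), c(2L, 3L))
  expect_error(expression_matrix(-v, scale = "raw_counts"), "negative")
  expect_error(expression_matrix(v, gene_names = c("a", "a", "b")), "unique")
  expect_error(reference_profiles(matrix(-1, 1, 1, dimnames = list("p", "g"))),
               "negative")
})

test_that("nc_vector must lie on the simplex", {
  expect_s3_class(nc_vector(c(0.2, 0.8)), "nc_vector")
  expect_error(nc_vector(c(0.5, 0.6)), "sum")
  expect_error(nc_vector(c(-0.1, 1.1)), "negative")
})

test_that("log_normalize and unlog_normalize are exact inverses", {
  v <- matrix(rpois(20, 5), 4, 5, dimnames = list(NULL, paste0("g", 1:5)))
  e <- expression_matrix(v, scale = "raw_counts")
  l <- log_normalize(e)
  expect_identical(l$scale, "log_normalized")
  expect_equal(l$values, log1p(v), ignore_attr = TRUE)
  back <- unlog_normalize(l)
  expect_equal(back$values, v, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("standardize_patch applies per-channel affine transform", {
  p <- he_patch(array(rep(c(12, 20, 35), each = 4), c(2, 2, 3)), mpp = 1)
  mu <- c(10, 10, 10); sd <- c(2, 4, 5)
  z <- standardize_patch(p, mu, sd)
  expect_equal(z[1, 1, 1], (p$pixels[1, 1, 1] - 10) / 2)
  expect_error(standardize_patch(p, mu, c(0, 1, 1)))
})

test_that("channel_stats matches direct pooled moments", {
  ps <- list(he_patch(array(10, c(2, 2, 3)), mpp = 1),
             he_patch(array(30, c(2, 2, 3)), mpp = 1))
  cs <- channel_stats(ps)
  expect_equal(cs$mean, rep(20, 3))
  expect_equal(cs$sd, rep(stats::sd(c(rep(10, 4), rep(30, 4))), 3))
})

test_that("image and label-map files round trip bit-exactly", {
  d <- withr::local_tempdir()
  p <- he_patch(array(sample(0:255, 16 * 16 * 3, TRUE), c(16, 16, 3)), mpp = 0.5)
  write_he_patch(p, file.path(d, "p.png"))
  expect_identical(read_he_patch(file.path(d, "p.png"), mpp = 0.5)$pixels, p$pixels)
  write_he_patch(p, file.path(d, "p.tif"))
  expect_identical(read_he_patch(file.path(d, "p.tif"), mpp = 0.5)$pixels, p$pixels)
  lab <- matrix(0L, 16, 16); lab[3:5, 3:5] <- 7L; lab[10:12, 10:14] <- 60000L
  write_instance_map(instance_map(lab), file.path(d, "m.tif"))
  expect_identical(read_instance_map(file.path(d, "m.tif"))$labels, lab)
  expect_error(write_instance_map(instance_map(matrix(70000L, 2, 2)),
                                  file.path(d, "x.tif")), "16-bit")
})

test_that("expression CSV and MatrixMarket files round trip", {
  d <- withr::local_tempdir()
  v <- matrix(rpois(20, 3), 4, 5, dimnames = list(NULL, paste0("g", 1:5)))
  e <- expression_matrix(v, scale = "raw_counts")
  write_expression_csv(e, file.path(d, "e.csv"))
  e2 <- read_expression_csv(file.path(d, "e.csv"))
  expect_equal(e2$values, e$values, ignore_attr = TRUE)
  expect_identical(e2$gene_names, e$gene_names)
  write_expression_mtx(e, file.path(d, "e"), cell_ids = paste0("c", 1:4))
  m <- read_expression_mtx(file.path(d, "e"))
  expect_equal(m$expr$values, e$values, ignore_attr = TRUE)
  expect_identical(m$cell_ids, paste0("c", 1:4))
})

test_that("reference profile CSV round trips with row labels", {
  d <- withr::local_tempdir()
  R <- matrix(c(1.5, 2, 3, 4.25), 2, 2,
              dimnames = list(c("typeA", "typeB"), c("g1", "g2")))
  ref <- reference_profiles(R)
  write_reference_csv(ref, file.path(d, "r.csv"))
  r2 <- read_reference_csv(file.path(d, "r.csv"))
  expect_equal(r2$R, ref$R)
  expect_identical(r2$profile_names, c("typeA", "typeB"))
})
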