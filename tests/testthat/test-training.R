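test_that("total loss applies the documented scalings", {
  nms <- c("L_Morph", "L_CT_class", "L_CT_embed", "L_CT_logits", "L_CT_expr",
           "L_NC_est", "L_NC_pr", "L_GE_adj", "L_GE")
  ones <- as.list(stats::setNames(rep(1, 9), nms))
  expect_identical(total_loss(ones, n_ct_aux = 5), 107.2)
  # general linear form
  vals <- as.list(stats::setNames(c(0.5, 2, 0.01, 3, 1, 0.2, 0.3, 4, 1.5), nms))
  expect_equal(total_loss(vals, n_ct_aux = 4),
               0.5 + 2 + 100 * 0.01 + 3 + 1 + 0.2 + 0.3 + 4 / 4 + 1.5)
  expect_error(total_loss(ones[-1], n_ct_aux = 5), "missing components")
})

test_that("augmentation preserves pixel multisets and map alignment", {
  set.seed(1)
  patch <- array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3))
  lab <- matrix(sample(0:3, 64, TRUE), 8, 8)
  for (code in c("identity", "hflip", "vflip", "rot90", "rot180", "rot270")) {
    tp <- histex:::apply_dihedral(patch, code)
    tl <- histex:::apply_dihedral(lab, code)
    expect_identical(sort(as.numeric(tp)), sort(as.numeric(patch)))
    expect_identical(tabulate(tl + 1L, 4L), tabulate(lab + 1L, 4L))
    # alignment: the label under a marked pixel moves with the pixel
    marked <- patch
    marked[2, 3, 1] <- 999
    tm <- histex:::apply_dihedral(marked, code)
    pos <- which(tm[, , 1] == 999, arr.ind = TRUE)
    expect_identical(tl[pos[1], pos[2]], lab[2, 3])
  }
  a <- augment(patch, list(lab))
  expect_true(a$transform %in% c("identity", "hflip", "vflip",
                                 "rot90", "rot180", "rot270"))
  expect_identical(dim(a$patch), dim(patch))
})

test_that("rotations compose as expected", {
  m <- matrix(1:12, 3, 4)
  r90 <- histex:::apply_dihedral(m, "rot90")
  expect_identical(dim(r90), c(4L, 3L))
  expect_identical(histex:::apply_dihedral(r90, "rot90"),
                   histex:::apply_dihedral(m, "rot180"))
})

test_that("AdamW matches a hand-computed first step", {
  cfg <- train_config(lr = 0.1, beta1 = 0.9, beta2 = 0.99, weight_decay = 0.01)
  params <- list(w = matrix(2, 1, 1))
  grads <- list(w = matrix(0.5, 1, 1))
  st <- histex:::adamw_init(params)
  out <- histex:::adamw_step(params, grads, st, cfg)
  m_hat <- (0.1 * 0.5) / (1 - 0.9)
  v_hat <- (0.01 * 0.25) / (1 - 0.99)
  expected <- 2 - 0.1 * (m_hat / (sqrt(v_hat) + 1e-8) + 0.01 * 2)
  expect_equal(as.numeric(out$params$w), expected, tolerance = 1e-12)
  expect_identical(out$state$t, 1L)
})

test_that("checkpoint selection minimizes the mean rank with earliest-epoch ties", {
  expect_identical(select_checkpoint(c(0.9, 0.8, 0.7), c(0.1, 0.3, 0.2)), 2L)
  # symmetric ranks tie; the earliest epoch wins
  expect_identical(select_checkpoint(c(0.9, 0.8), c(0.8, 0.9)), 1L)
  expect_identical(select_checkpoint(0.5, 0.5), 1L)
})

test_that("training is deterministic under the config seed and decreases the loss", {
  items <- tiny_items()
  m <- tiny_model()
  tc <- train_config(epochs = 2L, batch_size = 2L, seed = 5L)
  f1 <- train_model(items[1:3], items[4], m, tc, verbose = FALSE)
  f2 <- train_model(items[1:3], items[4], m, tc, verbose = FALSE)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$metrics$train_loss, f2$metrics$train_loss)
  expect_lt(f1$metrics$train_loss[2], f1$metrics$train_loss[1])
  # different seed gives a different trajectory
  f3 <- train_model(items[1:3], items[4], m,
                    train_config(epochs = 2L, batch_size = 2L, seed = 6L),
                    verbose = FALSE)
  expect_false(identical(f1$metrics$train_loss, f3$metrics$train_loss))
})

test_that("fit metrics carry all nine loss components and tidiers work", {
  items <- tiny_items()
  fit <- train_model(items[1:3], items[4], tiny_model(),
                     train_config(epochs = 2L, batch_size = 2L, seed = 5L),
                     verbose = FALSE)
  comps <- c("L_Morph", "L_CT_class", "L_CT_embed", "L_CT_logits", "L_CT_expr",
             "L_NC_est", "L_NC_pr", "L_GE_adj", "L_GE")
  expect_true(all(comps %in% names(fit$metrics)))
  td <- tidy(fit)
  expect_identical(sum(td$selected), 1L)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$epochs, 2L)
  pl <- ggplot2::autoplot(fit)
  expect_s3_class(pl, "ggplot")
})

test_that("checkpoints save and load with a manifest sidecar", {
  d <- withr::local_tempdir()
  m <- tiny_model()
  stem <- file.path(d, "ckpt")
  save_checkpoint(m, stem)
  expect_true(file.exists(paste0(stem, ".rds")))
  manifest <- jsonlite::read_json(paste0(stem, ".json"))
  expect_identical(manifest$mode, "reference")
  expect_identical(length(manifest$genes), 12L)
  m2 <- load_checkpoint(stem)
  expect_identical(m2$params, m$params)
})

test_that("training rejects item sets without any nucleus", {
  items <- tiny_items()
  empty <- items[[1]]
  empty$type_idx <- integer(0)
  empty$map <- instance_map(matrix(0L, 64, 64))
  expect_error(train_model(list(empty), list(), tiny_model(),
                           train_config(epochs = 1L), verbose = FALSE),
               "no training patch contains a valid nucleus")
})
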