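test_that("model initialization covers every head and respects the reference scale", {
  ds <- tiny_dataset()
  m <- tiny_model()
  expect_identical(m$config$mode, "reference")
  expect_equal(m$config$R_log, log1p(ds$ref$R), ignore_attr = TRUE)
  pn <- names(m$params)
  for (pre in c("bb.", "embed.", "ct.", "cons.", "nc.", "expr.wref.",
                "expr.att.", "adj.type1.")) {
    expect_true(any(startsWith(pn, pre)), label = paste("has", pre))
  }
  # backbone output classes = types + background
  expect_identical(m$config$backbone$n_classes, 4L)
  expect_error(hx_model_init(ds$ref$gene_names, "typeX",
                             reference = ds$ref, target_types = "zzz"),
               "target_types")
  expect_error(hx_model_init(rev(ds$ref$gene_names), paste0("type", 1:3),
                             reference = ds$ref), "gene order")
})

test_that("direct mode works without a reference", {
  ds <- tiny_dataset()
  bb <- backbone_config(levels = 4L, base_width = 4L, skip_width = 4L,
                        n_convs = 1L)
  m <- hx_model_init(ds$ref$gene_names, paste0("type", 1:3), reference = NULL,
                     backbone = bb, embed_dim = 16L, head_hidden = 16L,
                     n_heads = 2L, d_head = 4L, seed = 2L)
  expect_identical(m$config$mode, "direct")
  expect_true(any(startsWith(names(m$params), "expr.direct.")))
  cs <- channel_stats(ds$patches)
  m$channel_mean <- cs$mean; m$channel_sd <- cs$sd
  fw <- histex:::hx_forward_patch(m, ds$patches[[1]], ds$maps[[1]])
  expect_identical(ncol(fw$y_prime), 12L)
  expect_true(all(fw$y_prime >= 0))
})

test_that("model initialization is deterministic in the seed", {
  ds <- tiny_dataset()
  args <- list(gene_names = ds$ref$gene_names, cell_types = paste0("type", 1:3),
               reference = ds$ref,
               backbone = backbone_config(levels = 3L, base_width = 2L,
                                          skip_width = 2L, n_convs = 1L),
               embed_dim = 8L, head_hidden = 8L, n_heads = 1L, d_head = 4L)
  a <- do.call(hx_model_init, c(args, seed = 11L))
  b <- do.call(hx_model_init, c(args, seed = 11L))
  c <- do.call(hx_model_init, c(args, seed = 12L))
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
})

test_that("graph loss components agree with the standalone loss functions", {
  m <- tiny_model()
  it <- histex:::item_tensors(tiny_items()[[1]], m, FALSE)
  pn <- lapply(m$params, histex:::ag_leaf)
  g <- histex:::hx_graph(m, pn, it)
  comp <- g$components
  # morphology: oracle on the softmax of the backbone logits
  probs <- histex:::cpp_softmax_spatial(g$bb$logits$value)
  mask <- it$target_map >= 0L
  manual <- 0
  for (i in seq_len(nrow(it$target_map))) {
    for (j in seq_len(ncol(it$target_map))) {
      if (it$target_map[i, j] >= 0L) {
        manual <- manual - log(max(probs[i, j, it$target_map[i, j] + 1L], 1e-8))
      }
    }
  }
  expect_equal(comp[["L_Morph"]], manual / sum(mask), tolerance = 1e-10)
  # cell-type head
  expect_equal(comp[["L_CT_class"]],
               celltype_class_loss(g$ct_logits$value, it$type_idx),
               tolerance = 1e-10)
  # consistency heads against the standalone implementation
  cons <- list(W1 = m$params[["cons.W1"]], b1 = m$params[["cons.b1"]],
               W2 = m$params[["cons.W2"]], b2 = m$params[["cons.b2"]])
  cl <- consistency_losses(g$y_prime$value, it$y_log, it$type_idx, cons)
  expect_equal(comp[["L_CT_expr"]], cl$L_CT_expr, tolerance = 1e-8)
  expect_equal(comp[["L_CT_embed"]], cl$L_CT_embed, tolerance = 1e-8)
  expect_equal(comp[["L_CT_logits"]], cl$L_CT_logits, tolerance = 1e-8)
  # composition losses
  probs_ct <- histex:::softmax_rows(g$ct_logits$value)
  nl <- nc_losses(as.numeric(g$p_est$value), colMeans(probs_ct), it$q_true)
  expect_equal(comp[["L_NC_est"]], nl$L_NC_est, tolerance = 1e-10)
  expect_equal(comp[["L_NC_pr"]], nl$L_NC_pr, tolerance = 1e-10)
  # expression loss
  expect_equal(comp[["L_GE"]], expression_loss(g$y_prime$value, it$y_log),
               tolerance = 1e-10)
  # total equals the public scaling rule
  expect_equal(g$total$value,
               total_loss(as.list(comp), n_ct_aux = 3L), tolerance = 1e-10)
})

test_that("graph expression head matches the standalone algebra", {
  m <- tiny_model()
  it <- histex:::item_tensors(tiny_items()[[2]], m, FALSE)
  pn <- lapply(m$params, histex:::ag_leaf)
  g <- histex:::hx_graph(m, pn, it)
  xn <- g$x_nucleus$value
  wp <- list(W1 = m$params[["expr.wref.W1"]], b1 = m$params[["expr.wref.b1"]],
             W2 = m$params[["expr.wref.W2"]], b2 = m$params[["expr.wref.b2"]])
  W <- predict_weights(xn, wp)
  S <- weighted_profile(W, m$config$R_log)
  att <- list(Wq = m$params[["expr.att.Wq"]], G = m$params[["expr.att.G"]],
              H = m$params[["expr.att.H"]], Wo = m$params[["expr.att.Wo"]],
              bo = m$params[["expr.att.bo"]],
              n_heads = m$config$n_heads, d_head = m$config$d_head)
  b <- attention_residual(as.numeric(g$p_est$value), S, att)
  y <- finalize_expression(S, b, "reference")
  expect_equal(unname(g$y_prime$value), unname(y), tolerance = 1e-10)
})

test_that("spot-mode items supervise the summed prediction", {
  m <- tiny_model()
  it <- histex:::item_tensors(tiny_items()[[1]], m, FALSE)
  it$type_idx <- NULL; it$y_log <- NULL; it$q_true <- NULL
  it$y_spot <- abs(rnorm(12))
  pn <- lapply(m$params, histex:::ag_leaf)
  g <- histex:::hx_graph(m, pn, it)
  manual <- mean((colSums(g$y_prime$value) - it$y_spot)^2)
  expect_equal(g$components[["L_GE"]], manual, tolerance = 1e-10)
  expect_identical(g$components[["L_CT_class"]], 0)
})
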