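# Reverse-mode gradients of every operator are checked against central
# finite differences on smooth losses.

ag <- function(f) getFromNamespace(f, "histex")

fd_check <- function(build, params, tol = 1e-4, n_probe = 4L) {
  leaf <- ag("ag_leaf")
  pn <- lapply(params, leaf)
  loss <- build(pn)
  ag("ag_backward")(loss)
  for (nm in names(params)) {
    p <- params[[nm]]
    for (i in sample(length(p), min(n_probe, length(p)))) {
      h <- 1e-6
      f <- function(v) {
        pp <- params
        pp[[nm]][i] <- v
        build(lapply(pp, leaf))$value
      }
      fd <- (f(p[i] + h) - f(p[i] - h)) / (2 * h)
      an <- as.numeric(pn[[nm]]$grad)[i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), tol)
    }
  }
}

test_that("convolution gradients match finite differences", {
  set.seed(1)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  w <- matrix(rnorm(27 * 4) * 0.3, 27, 4)
  b <- rnorm(4)
  fd_check(function(pn) ag("ag_mse")(ag("ag_conv2d")(pn$x, pn$w, pn$b),
                                     array(0.3, c(8, 8, 4))),
           list(x = x, w = w, b = b))
})

test_that("pooling and resizing gradients match finite differences", {
  set.seed(2)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  fd_check(function(pn) ag("ag_mse")(ag("ag_maxpool2")(pn$x),
                                     array(0.1, c(4, 4, 3))), list(x = x))
  fd_check(function(pn) ag("ag_mse")(ag("ag_blockmean")(pn$x, 2L),
                                     array(0.1, c(4, 4, 3))), list(x = x))
  fd_check(function(pn) ag("ag_mse")(ag("ag_upnearest")(pn$x, 2L),
                                     array(0.1, c(16, 16, 3))), list(x = x))
})

test_that("spatial cross-entropy gradient matches finite differences and honors ignore labels", {
  set.seed(3)
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  tg <- matrix(sample(0:2, 36, TRUE), 6, 6)
  tg[1, 1:3] <- -1L
  storage.mode(tg) <- "integer"
  fd_check(function(pn) ag("ag_spatial_ce")(pn$x, tg), list(x = x))
})

test_that("classification, composition and consistency loss gradients match finite differences", {
  set.seed(4)
  A <- matrix(rnorm(12), 3, 4); B <- matrix(rnorm(20), 4, 5); bias <- rnorm(5)
  fd_check(function(pn) ag("ag_ce_rows")(
    ag("ag_addbias")(ag("ag_matmul")(pn$A, pn$B), pn$bias), c(1L, 3L, 5L)),
    list(A = A, B = B, bias = bias))
  fd_check(function(pn) ag("ag_kl")(ag("ag_softmax_rows")(pn$A),
                                    c(0.1, 0.2, 0.3, 0.4)),
           list(A = matrix(rnorm(4), 1, 4)))
  E1 <- matrix(rnorm(15), 3, 5); E2 <- matrix(rnorm(15), 3, 5)
  fd_check(function(pn) ag("ag_cosine_loss")(pn$E1, pn$E2),
           list(E1 = E1, E2 = E2))
})

test_that("pooling-over-nuclei and broadcast gradients match finite differences", {
  set.seed(5)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  pix <- list(c(1L, 2L, 9L), c(20L, 21L), 40:45)
  fd_check(function(pn) ag("ag_mse")(ag("ag_mask_pool")(pn$x, pix),
                                     matrix(0.2, 3, 3)), list(x = x))
  E <- matrix(rnorm(15), 3, 5)
  fd_check(function(pn) ag("ag_mse")(
    ag("ag_rep_rows")(ag("ag_colmeans")(pn$E), 3L), matrix(0.1, 3, 5)),
    list(E = E))
  fd_check(function(pn) ag("ag_mse")(ag("ag_spatial_meanvec")(pn$x),
                                     matrix(0.2, 1, 3)), list(x = x))
})

test_that("slicing, transposition and concatenation route gradients correctly", {
  set.seed(6)
  A <- matrix(rnorm(20), 4, 5)
  fd_check(function(pn) ag("ag_mse")(ag("ag_slice_cols")(pn$A, 2:3),
                                     matrix(0, 4, 2)), list(A = A))
  fd_check(function(pn) ag("ag_mse")(ag("ag_slice_rows")(pn$A, c(1L, 4L)),
                                     matrix(0, 2, 5)), list(A = A))
  fd_check(function(pn) ag("ag_mse")(ag("ag_transpose")(pn$A),
                                     matrix(0, 5, 4)), list(A = A))
  B <- matrix(rnorm(8), 4, 2)
  fd_check(function(pn) ag("ag_mse")(ag("ag_concat_cols")(list(pn$A, pn$B)),
                                     matrix(0, 4, 7)), list(A = A, B = B))
})

test_that("gradients accumulate over shared subexpressions", {
  leaf <- ag("ag_leaf")
  a <- leaf(matrix(2, 1, 1))
  # loss = (a * a) + a  => dL/da = 2a + 1 = 5
  loss <- ag("ag_sum")(ag("ag_add")(ag("ag_mul")(a, a), a))
  ag("ag_backward")(loss)
  expect_equal(as.numeric(a$grad), 5)
})

test_that("the full multitask graph is differentiable end to end", {
  m <- tiny_model()
  items <- tiny_items()
  it <- histex:::item_tensors(items[[1]], m, FALSE)
  pn <- lapply(m$params, histex:::ag_leaf)
  g <- histex:::hx_graph(m, pn, it)
  histex:::ag_backward(g$total)
  expect_true(is.finite(g$total$value))
  # every parameter that feeds the graph receives a finite gradient
  grads <- lapply(pn, function(p) p$grad)
  n_with <- sum(!vapply(grads, is.null, TRUE))
  expect_gt(n_with, 0.9 * length(grads))
  expect_true(all(vapply(grads[!vapply(grads, is.null, TRUE)],
                         function(g) all(is.finite(g)), TRUE)))
  # directional probe against finite differences on a smooth head parameter
  nm <- "ct.W2"
  i <- 1L
  h <- 1e-6
  loss_at <- function(v) {
    pp <- m$params
    pp[[nm]][i] <- v
    pn2 <- lapply(pp, histex:::ag_leaf)
    histex:::hx_graph(m, pn2, it)$total$value
  }
  fd <- (loss_at(m$params[[nm]][i] + h) - loss_at(m$params[[nm]][i] - h)) / (2 * h)
  an <- as.numeric(grads[[nm]])[i]
  expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
})
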