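# Minimal reverse-mode automatic differentiation on a dynamically built tape.
# Nodes are environments holding a value, an accumulated gradient, parent
# references and a backward closure that maps the node's gradient to the
# parents' gradients. Everything the network needs composes from the ops
# below; convolution/pooling kernels live in src/.

.ag_env <- new.env(parent = emptyenv())
.ag_env$counter <- 0L

ag_node <- function(value, parents = list(), backward = NULL) {
  .ag_env$counter <- .ag_env$counter + 1L
  e <- new.env(parent = emptyenv())
  e$id <- .ag_env$counter
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  class(e) <- "ag_node"
  e
}

#' Wrap an array as an autograd leaf
#'
#' Leaves are the trainable parameters (or inputs); their gradients are
#' populated by [ag_backward()].
#'
#' @param value numeric vector, matrix or array.
#' @return An `ag_node`.
#' @keywords internal
ag_leaf <- function(value) ag_node(value)

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

.ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Run reverse-mode differentiation from a scalar loss node
#'
#' Accumulates gradients into the `grad` fields of every ancestor node.
#' Gradients add up across calls; zero them by rebuilding the tape (the
#' training loop wraps parameters in fresh leaves each step).
#'
#' @param loss an `ag_node` holding a scalar.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  # iterative post-order DFS to get a topological order
  topo <- vector("list", 256L)
  nt <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is.null(visited[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- node
    }
  }
  loss$grad <- 1
  for (k in seq(nt, 1L)) {
    node <- topo[[k]]
    if (!is.null(node$backward) && !is.null(node$grad)) {
      gs <- node$backward(node$grad)
      for (i in seq_along(node$parents)) {
        if (!is.null(gs[[i]])) .ag_accum(node$parents[[i]], gs[[i]])
      }
    }
  }
  invisible(loss)
}

# ---- elementwise / linear algebra ops ----------------------------------

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  ag_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(a, s) {
  ag_node(a$value * s, list(a), function(g) list(g * s))
}

ag_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_node(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

# matrix + row-vector bias broadcast over rows
ag_addbias <- function(a, b) {
  bv <- as.numeric(b$value)
  v <- sweep(a$value, 2L, bv, "+")
  ag_node(v, list(a, b), function(g) list(g, colSums(g)))
}

ag_relu <- function(a) {
  mask <- a$value > 0
  ag_node(a$value * mask, list(a), function(g) list(g * mask))
}

ag_mean <- function(a) {
  n <- length(a$value)
  ag_node(mean(a$value), list(a), function(g) list(array(g / n, dim = dim(a$value) %||% length(a$value))))
}

ag_sum <- function(a) {
  ag_node(sum(a$value), list(a), function(g) {
    list(array(g, dim = dim(a$value) %||% length(a$value)))
  })
}

ag_wsum <- function(nodes, weights) {
  v <- 0
  for (i in seq_along(nodes)) v <- v + weights[i] * nodes[[i]]$value
  ag_node(v, nodes, function(g) lapply(seq_along(nodes), function(i) g * weights[i]))
}

ag_slice_cols <- function(a, idx) {
  av <- a$value
  ag_node(av[, idx, drop = FALSE], list(a), function(g) {
    gx <- array(0, dim = dim(av))
    gx[, idx] <- g
    list(gx)
  })
}

ag_concat_cols <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ag_vcat <- function(nodes) {
  # concatenate row vectors (1 x k matrices) into one row vector
  ag_concat_cols(nodes)
}

# replicate a 1 x d row vector to n rows
ag_rep_rows <- function(a, n) {
  av <- a$value
  ag_node(matrix(av, nrow = n, ncol = length(av), byrow = TRUE), list(a),
          function(g) list(matrix(colSums(g), nrow = 1L)))
}

ag_colmeans <- function(a) {
  n <- nrow(a$value)
  ag_node(matrix(colMeans(a$value), nrow = 1L), list(a), function(g) {
    list(matrix(as.numeric(g), nrow = n, ncol = ncol(a$value), byrow = TRUE) / n)
  })
}

# ---- softmax and losses ------------------------------------------------

ag_softmax_rows <- function(a) {
  z <- a$value
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  ag_node(p, list(a), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

#' Mean cross-entropy of row logits against integer classes
#' @param a `ag_node`, n x M logits.
#' @param target integer vector of 1-based classes, length n.
#' @keywords internal
ag_ce_rows <- function(a, target, eps = 1e-8) {
  z <- a$value
  n <- nrow(z)
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  pt <- pmax(p[cbind(seq_len(n), target)], eps)
  ag_node(-mean(log(pt)), list(a), function(g) {
    gz <- p
    gz[cbind(seq_len(n), target)] <- gz[cbind(seq_len(n), target)] - 1
    list(g * gz / n)
  })
}

#' Mean squared error against a constant target
#' @keywords internal
ag_mse <- function(a, target) {
  d <- a$value - target
  n <- length(d)
  ag_node(mean(d^2), list(a), function(g) list(g * 2 * d / n))
}

#' Mean (1 - cosine similarity) between paired rows of two matrices
#' @keywords internal
ag_cosine_loss <- function(a, b, eps = 1e-8) {
  av <- a$value; bv <- b$value
  n <- nrow(av)
  na <- pmax(sqrt(rowSums(av^2)), eps)
  nb <- pmax(sqrt(rowSums(bv^2)), eps)
  dot <- rowSums(av * bv)
  cosv <- dot / (na * nb)
  ag_node(mean(1 - cosv), list(a, b), function(g) {
    ga <- -(bv / (na * nb) - av * (dot / (na^3 * nb))) / n
    gb <- -(av / (na * nb) - bv * (dot / (nb^3 * na))) / n
    list(g * ga, g * gb)
  })
}

#' KL divergence of a probability vector node from a constant target
#'
#' `sum(p * log(p / q))` with the ratio clamped below at `eps`; natural log.
#' @keywords internal
ag_kl <- function(a, q, eps = 1e-8) {
  p <- as.numeric(a$value)
  r <- pmax(p, eps) / pmax(q, eps)
  lr <- log(r)
  ag_node(sum(p * lr), list(a), function(g) {
    gx <- g * (lr + 1)
    dim(gx) <- dim(a$value)
    list(gx)
  })
}

# ---- spatial ops (cubes H x W x C) -------------------------------------

ag_conv2d <- function(x, w, b, kh = 3L, kw = 3L) {
  xv <- x$value; wv <- w$value; bv <- as.numeric(b$value)
  y <- cpp_conv2d_fw(xv, wv, bv, kh, kw)
  ag_node(y, list(x, w, b), function(g) {
    bw <- cpp_conv2d_bw(xv, wv, g, kh, kw)
    list(bw$gx, bw$gw, bw$gb)
  })
}

ag_maxpool2 <- function(x) {
  xv <- x$value
  fw <- cpp_maxpool2_fw(xv)
  ag_node(fw$y, list(x), function(g) {
    list(cpp_maxpool2_bw(fw$idx, g, dim(xv)[1], dim(xv)[2]))
  })
}

ag_blockmean <- function(x, k) {
  xv <- x$value
  ag_node(cpp_block_mean(xv, k), list(x), function(g) {
    list(cpp_replicate(g, k) / (k * k))
  })
}

ag_upnearest <- function(x, k) {
  ag_node(cpp_replicate(x$value, k), list(x), function(g) {
    list(cpp_block_mean(g, k) * (k * k))
  })
}

ag_concat_c <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  ch <- vapply(vals, function(v) dim(v)[3], 1L)
  ends <- cumsum(ch)
  starts <- ends - ch + 1L
  v <- array(0, dim = c(dim(vals[[1]])[1:2], sum(ch)))
  for (i in seq_along(vals)) v[, , starts[i]:ends[i]] <- vals[[i]]
  ag_node(v, nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, , starts[i]:ends[i], drop = FALSE])
  })
}

#' Spatial cross-entropy on per-pixel logits
#' @param x `ag_node`, H x W x M logit cube.
#' @param target integer H x W matrix of 0-based classes (-1 = ignore).
#' @keywords internal
ag_spatial_ce <- function(x, target, eps = 1e-8) {
  storage.mode(target) <- "integer"
  fw <- cpp_softmax_ce_spatial(x$value, target, eps)
  ag_node(fw$loss, list(x), function(g) list(g * fw$grad))
}

# mean of each channel over all pixels -> 1 x C row vector
ag_spatial_meanvec <- function(x) {
  xv <- x$value
  d <- dim(xv)
  np <- d[1] * d[2]
  m <- matrix(xv, nrow = np, ncol = d[3])
  ag_node(matrix(colMeans(m), nrow = 1L), list(x), function(g) {
    gx <- matrix(as.numeric(g), nrow = np, ncol = d[3], byrow = TRUE) / np
    dim(gx) <- d
    list(gx)
  })
}

#' Mask-pool a feature cube over nuclei
#'
#' For each nucleus, sums the features over its pixels and divides by the
#' pixel area (mean pooling over the mask), countering nucleus-size
#' variability.
#'
#' @param x `ag_node`, H x W x C feature cube.
#' @param pix list of integer vectors of linear pixel indices (1-based into
#'   the H x W plane), one per nucleus.
#' @return `ag_node` holding an n_nuclei x C matrix.
#' @keywords internal
ag_mask_pool <- function(x, pix) {
  xv <- x$value
  d <- dim(xv)
  np <- d[1] * d[2]
  m <- matrix(xv, nrow = np, ncol = d[3])
  n <- length(pix)
  out <- matrix(0, n, d[3])
  for (i in seq_len(n)) {
    out[i, ] <- colSums(m[pix[[i]], , drop = FALSE]) / length(pix[[i]])
  }
  ag_node(out, list(x), function(g) {
    gm <- matrix(0, np, d[3])
    for (i in seq_len(n)) {
      gm[pix[[i]], ] <- gm[pix[[i]], ] +
        matrix(g[i, ] / length(pix[[i]]), nrow = length(pix[[i]]), ncol = d[3], byrow = TRUE)
    }
    dim(gm) <- d
    list(gm)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
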