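# Full multitask model: backbone + per-nucleus embedding + cell-type,
# consistency, neighborhood-composition and expression heads, assembled
# into a single differentiable training graph.

flatten_params <- function(prefix, p) {
  stats::setNames(p, paste0(prefix, ".", names(p)))
}

#' Initialize the multitask model
#'
#' Creates every parameter of the framework with He initialization:
#' the segmentation backbone, the two-layer nucleus embedding, the
#' cell-type head, the shared expression-to-cell-type consistency head,
#' the neighborhood-composition head, the expression regressor (reference
#' mode: profile-weight head + cross-attention; direct mode: straight
#' regression + cross-attention) and one adjusted expression head per
#' target type.
#'
#' @param gene_names gene panel (ordered).
#' @param cell_types cell-type labels (ordered; defines class indices).
#' @param reference optional [reference_profiles()]; its presence selects
#'   reference mode, its absence direct mode.
#' @param reference_scale scale of the supplied profiles; raw counts are
#'   log1p-transformed to match the log-normalized expression targets.
#' @param backbone a [backbone_config()]; `n_classes` is overridden to
#'   `length(cell_types) + 1`.
#' @param embed_dim nucleus embedding size (default 256).
#' @param head_hidden hidden width of the prediction heads (default 256).
#' @param n_heads,d_head cross-attention geometry (default 8 x 64).
#' @param target_types types receiving an adjusted expression head and
#'   subject to recovery.
#' @param seed integer seed for parameter initialization.
#' @return An object of class `hx_model`.
#' @export
hx_model_init <- function(gene_names, cell_types, reference = NULL,
                          reference_scale = c("raw_counts", "log_normalized"),
                          backbone = backbone_config(),
                          embed_dim = 256L, head_hidden = 256L,
                          n_heads = 8L, d_head = 64L,
                          target_types = character(), seed = 1L) {
  reference_scale <- match.arg(reference_scale)
  n_genes <- length(gene_names)
  M <- length(cell_types)
  stopifnot(M >= 1L, n_genes >= 1L)
  if (!all(target_types %in% cell_types)) {
    stop("hx_model_init: target_types must be a subset of cell_types")
  }
  bb <- backbone
  bb$n_classes <- M + 1L
  mode <- if (is.null(reference)) "direct" else "reference"
  R_log <- NULL
  if (mode == "reference") {
    stopifnot(inherits(reference, "reference_profiles"))
    if (!identical(reference$gene_names, gene_names)) {
      stop("hx_model_init: reference gene order must match the panel")
    }
    R_log <- if (reference_scale == "raw_counts") log1p(reference$R) else reference$R
  }
  F2 <- bb$base_width + bb$last_channels
  params <- with_substream(seed, 7L, {
    p <- flatten_params("bb", backbone_init(bb))
    p <- c(p, flatten_params("embed", fc2_init(2L * F2, head_hidden, embed_dim)))
    p <- c(p, flatten_params("ct", fc2_init(embed_dim, head_hidden, M)))
    p <- c(p, flatten_params("cons", fc2_init(n_genes, head_hidden, M)))
    p <- c(p, flatten_params("nc", fc2_init(embed_dim, head_hidden, M)))
    expr_head <- function(prefix) {
      q <- if (mode == "reference") {
        flatten_params(paste0(prefix, ".wref"),
                       fc2_init(embed_dim, head_hidden, nrow(R_log)))
      } else {
        flatten_params(paste0(prefix, ".direct"),
                       fc2_init(embed_dim, head_hidden, n_genes))
      }
      att <- attention_init(M, n_genes, n_heads, d_head)
      att$n_heads <- NULL; att$d_head <- NULL
      c(q, flatten_params(paste0(prefix, ".att"), att))
    }
    p <- c(p, expr_head("expr"))
    for (t in target_types) p <- c(p, expr_head(paste0("adj.", t)))
    p
  })
  structure(list(
    params = params,
    config = list(backbone = bb, gene_names = gene_names,
                  cell_types = cell_types, mode = mode, R_log = R_log,
                  embed_dim = embed_dim, head_hidden = head_hidden,
                  n_heads = as.integer(n_heads), d_head = as.integer(d_head),
                  target_types = target_types, seed = as.integer(seed)),
    channel_mean = NULL, channel_sd = NULL),
    class = "hx_model")
}

#' @export
print.hx_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1))
  cat(sprintf("<hx_model> %s mode, %d genes, %d cell types, %s parameters\n",
              x$config$mode, length(x$config$gene_names),
              length(x$config$cell_types), format(np, big.mark = ",")))
  invisible(x)
}

# two-layer perceptron on the tape
fc2_ag <- function(x, pn, prefix) {
  h <- ag_relu(ag_addbias(ag_matmul(x, pn[[paste0(prefix, ".W1")]]),
                          pn[[paste0(prefix, ".b1")]]))
  ag_addbias(ag_matmul(h, pn[[paste0(prefix, ".W2")]]), pn[[paste0(prefix, ".b2")]])
}

# expression head (Eqs 9-13) on the tape; returns y' node and S node
expr_head_ag <- function(xn, p_est, model, pn, prefix) {
  cfg <- model$config
  if (cfg$mode == "reference") {
    Wl <- fc2_ag(xn, pn, paste0(prefix, ".wref"))
    Wsm <- ag_softmax_rows(Wl)
    S <- ag_matmul(Wsm, ag_leaf(cfg$R_log))
  } else {
    S <- fc2_ag(xn, pn, paste0(prefix, ".direct"))
  }
  n <- nrow(S$value)
  q <- ag_matmul(p_est, pn[[paste0(prefix, ".att.Wq")]])
  outs <- vector("list", cfg$n_heads)
  for (h in seq_len(cfg$n_heads)) {
    idx <- ((h - 1L) * cfg$d_head + 1L):(h * cfg$d_head)
    qh <- ag_slice_cols(q, idx)
    Gh <- ag_slice_cols(pn[[paste0(prefix, ".att.G")]], idx)
    Hh <- ag_slice_cols(pn[[paste0(prefix, ".att.H")]], idx)
    u <- ag_matmul(qh, ag_transpose(Gh))
    w0 <- ag_matmul(qh, ag_transpose(Hh))
    scores <- ag_scale(ag_add(ag_mul(S, ag_rep_rows(u, n)), ag_rep_rows(w0, n)),
                       1 / sqrt(cfg$d_head))
    a <- ag_softmax_rows(scores)
    outs[[h]] <- ag_add(ag_matmul(ag_mul(a, S), Gh), ag_matmul(a, Hh))
  }
  att <- ag_concat_cols(outs)
  b <- ag_addbias(ag_matmul(att, pn[[paste0(prefix, ".att.Wo")]]),
                  pn[[paste0(prefix, ".att.bo")]])
  y <- if (cfg$mode == "reference") ag_relu(ag_add(S, b)) else ag_relu(b)
  list(y = y, S = S, b = b)
}

# Build the full multitask graph for one training item. `pn` holds the
# parameter leaves; `item` carries x_std (standardized patch array),
# target_map (0-based class matrix, -1 = ignore), pix (per-nucleus pixel
# index lists), type_idx (1-based per-nucleus types or NULL), y_log
# (per-nucleus log-normalized expression or NULL), q_true (composition or
# NULL), y_spot / spot mode fields optional.
hx_graph <- function(model, pn, item) {
  cfg <- model$config
  M <- length(cfg$cell_types)
  zero <- function() ag_leaf(0)
  bbn <- pn[startsWith(names(pn), "bb.")]
  names(bbn) <- substring(names(bbn), 4L)
  bb <- bb_forward_ag(ag_leaf(item$x_std), cfg$backbone, bbn)
  L_morph <- if (!is.null(item$target_map)) {
    ag_spatial_ce(bb$logits, item$target_map)
  } else zero()
  comp <- list(L_Morph = L_morph, L_CT_class = zero(), L_CT_embed = zero(),
               L_CT_logits = zero(), L_CT_expr = zero(), L_NC_est = zero(),
               L_NC_pr = zero(), L_GE_adj = zero(), L_GE = zero())
  out <- list(bb = bb)
  n <- length(item$pix)
  if (n > 0L) {
    feat <- ag_concat_c(list(bb$first, bb$last))
    pooled <- ag_mask_pool(feat, item$pix)
    pv <- ag_spatial_meanvec(feat)
    z <- ag_concat_cols(list(pooled, ag_rep_rows(pv, n)))
    xn <- fc2_ag(z, pn, "embed")
    ct_logits <- fc2_ag(xn, pn, "ct")
    ct_probs <- ag_softmax_rows(ct_logits)
    p_est <- ag_softmax_rows(fc2_ag(ag_colmeans(xn), pn, "nc"))
    expr <- expr_head_ag(xn, p_est, model, pn, "expr")
    out$x_nucleus <- xn
    out$ct_logits <- ct_logits
    out$p_est <- p_est
    out$y_prime <- expr$y
    if (!is.null(item$type_idx)) {
      comp$L_CT_class <- ag_ce_rows(ct_logits, item$type_idx)
    }
    if (!is.null(item$q_true)) {
      comp$L_NC_est <- ag_kl(p_est, item$q_true)
      comp$L_NC_pr <- ag_kl(ag_colmeans(ct_probs), item$q_true)
    }
    if (!is.null(item$y_log)) {
      comp$L_GE <- ag_mse(expr$y, item$y_log)
      if (!is.null(item$type_idx)) {
        # shared consistency head on predicted and ground-truth expression
        emb <- function(y) ag_relu(ag_addbias(ag_matmul(y, pn[["cons.W1"]]),
                                              pn[["cons.b1"]]))
        head2 <- function(h) ag_addbias(ag_matmul(h, pn[["cons.W2"]]),
                                        pn[["cons.b2"]])
        e_pr <- emb(expr$y); e_gt <- emb(ag_leaf(item$y_log))
        l_pr <- head2(e_pr); l_gt <- head2(e_gt)
        comp$L_CT_expr <- ag_ce_rows(l_pr, item$type_idx)
        comp$L_CT_embed <- ag_cosine_loss(e_pr, e_gt)
        dlog <- ag_sub(l_pr, l_gt)
        comp$L_CT_logits <- ag_mean(ag_mul(dlog, dlog))
        if (length(cfg$target_types) > 0L) {
          adj_terms <- list()
          for (t in cfg$target_types) {
            sel <- which(cfg$cell_types[item$type_idx] == t)
            if (length(sel) == 0L) next
            adj <- expr_head_ag(ag_slice_rows(xn, sel), p_est, model, pn,
                                paste0("adj.", t))
            adj_terms[[t]] <- ag_mse(adj$y, item$y_log[sel, , drop = FALSE])
          }
          if (length(adj_terms) > 0L) {
            comp$L_GE_adj <- ag_wsum(adj_terms, rep(1, length(adj_terms)))
          }
        }
      }
    }
    if (!is.null(item$y_spot)) {
      # weakly supervised spot mode: the spot prediction is the sum of the
      # per-cell predictions in the patch
      spot_pred <- ag_matmul(ag_leaf(matrix(1, 1L, n)), expr$y)
      comp$L_GE <- ag_mse(spot_pred, rbind(item$y_spot))
    }
  }
  weights <- c(1, 1, 100, 1, 1, 1, 1, 1 / M, 1)
  total <- ag_wsum(unname(comp), weights)
  out$components <- vapply(comp, function(x) x$value, numeric(1))
  out$total <- total
  out
}

ag_transpose <- function(a) {
  ag_node(t(a$value), list(a), function(g) list(t(g)))
}

ag_slice_rows <- function(a, idx) {
  av <- a$value
  ag_node(av[idx, , drop = FALSE], list(a), function(g) {
    gx <- array(0, dim = dim(av))
    gx[idx, ] <- g
    list(gx)
  })
}

# Value-only forward pass for one patch at inference time.
# Returns per-nucleus quantities for the valid nuclei of `map`.
hx_forward_patch <- function(model, patch, map, params = model$params) {
  cfg <- model$config
  x_std <- standardize_patch(patch, model$channel_mean, model$channel_sd)
  pix <- nucleus_pixels(map)
  pn <- lapply(params, ag_leaf)
  item <- list(x_std = x_std, target_map = NULL, pix = pix)
  g <- hx_graph(model, pn, item)
  if (length(pix) == 0L) {
    return(list(ids = integer(), ct_logits = NULL, ct_probs = NULL,
                p_est = numeric(length(cfg$cell_types)),
                y_prime = NULL, y_adj = list()))
  }
  ct_logits <- g$ct_logits$value
  probs <- softmax_rows(ct_logits)
  y_adj <- list()
  for (t in cfg$target_types) {
    adj <- expr_head_ag(g$x_nucleus, g$p_est, model, pn, paste0("adj.", t))
    y_adj[[t]] <- adj$y$value
  }
  list(ids = map$valid_ids, ct_logits = ct_logits, ct_probs = probs,
       p_est = as.numeric(g$p_est$value), y_prime = g$y_prime$value,
       y_adj = y_adj, seg_probs = cpp_softmax_spatial(g$bb$logits$value))
}
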