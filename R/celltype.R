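# Cell-type head, expression-to-cell-type consistency heads, neighborhood
# composition head, and the composition-guided recovery mechanism applied
# at inference.

softmax_rows <- function(z) {
  z <- rbind(z)
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Predict a cell type from a morphology embedding
#'
#' A fully connected layer with 256-dimensional intermediate features,
#' ReLU, and a second fully connected layer producing one logit per cell
#' type; the class is the argmax (ties broken toward the lowest index).
#'
#' @param x_nucleus embedding vector or `n x 256` matrix.
#' @param params two-layer parameters (see `fc2_init`).
#' @return list with `logits` (`n x M`) and `class` (integer vector of
#'   1-based type indices).
#' @export
predict_celltype <- function(x_nucleus, params) {
  logits <- fc2_apply(x_nucleus, params)
  list(logits = logits, class = apply(logits, 1L, which.max))
}

#' Cross-entropy of cell-type logits against true types
#'
#' Mean over cells of the negative log softmax probability of the true
#' type.
#'
#' @param logits `n x M` logit matrix.
#' @param types integer vector of 1-based true type indices.
#' @param eps probability clamp inside the log.
#' @return Scalar loss.
#' @export
celltype_class_loss <- function(logits, types, eps = 1e-8) {
  logits <- rbind(logits)
  stopifnot(nrow(logits) >= 1L, length(types) == nrow(logits))
  if (any(types < 1L | types > ncol(logits))) {
    stop("celltype_class_loss: unknown class label")
  }
  p <- softmax_rows(logits)
  -mean(log(pmax(p[cbind(seq_len(nrow(p)), types)], eps)))
}

#' Consistency losses between predicted- and truth-derived cell types
#'
#' A shared head maps each expression vector to a 256-dimensional embedding
#' (first layer + ReLU) and then to cell-type logits (second layer). The
#' three losses are: cross-entropy of the predicted-expression logits
#' against the true types (computed exclusively on the predicted input),
#' mean over cells of `1 - cos(embedding_pred, embedding_true)`, and the
#' mean squared difference between the two logit vectors.
#'
#' @param y_pred,y_true `n x n_genes` expression matrices (log scale).
#' @param types integer vector of 1-based true type indices.
#' @param params shared head parameters (see `fc2_init`).
#' @param eps clamp for cosine norms and log probabilities.
#' @return list with `L_CT_expr`, `L_CT_embed`, `L_CT_logits`.
#' @export
consistency_losses <- function(y_pred, y_true, types, params, eps = 1e-8) {
  y_pred <- rbind(y_pred); y_true <- rbind(y_true)
  stopifnot(all(dim(y_pred) == dim(y_true)), length(types) == nrow(y_pred))
  emb <- function(y) pmax(sweep(y %*% params$W1, 2L, params$b1, "+"), 0)
  head2 <- function(h) sweep(h %*% params$W2, 2L, params$b2, "+")
  e_pr <- emb(y_pred); e_gt <- emb(y_true)
  l_pr <- head2(e_pr); l_gt <- head2(e_gt)
  n_pr <- pmax(sqrt(rowSums(e_pr^2)), eps)
  n_gt <- pmax(sqrt(rowSums(e_gt^2)), eps)
  cosv <- rowSums(e_pr * e_gt) / (n_pr * n_gt)
  list(L_CT_expr = celltype_class_loss(l_pr, types, eps),
       L_CT_embed = mean(1 - cosv),
       L_CT_logits = mean((l_pr - l_gt)^2))
}

#' Estimate the neighborhood composition of a patch
#'
#' Averages the nucleus embeddings of the patch, applies two fully
#' connected layers with ReLU, and a softmax so the estimated cell-type
#' composition sums to 1. An empty patch returns an all-zero sentinel
#' (attribute `empty = TRUE`) that callers exclude from losses.
#'
#' @param x_nucleus `n x 256` embedding matrix (rows = nuclei in the
#'   patch).
#' @param params two-layer parameters with output size `n_CT`.
#' @return Numeric composition vector of length `n_CT`.
#' @export
estimate_nc <- function(x_nucleus, params) {
  x_nucleus <- rbind(x_nucleus)
  if (nrow(x_nucleus) == 0L) {
    out <- numeric(ncol(params$W2))
    attr(out, "empty") <- TRUE
    return(out)
  }
  as.numeric(softmax_rows(fc2_apply(matrix(colMeans(x_nucleus), nrow = 1L), params)))
}

#' Kullback-Leibler composition losses
#'
#' `L_NC_est = KL(p_est || q)` for the composition head and
#' `L_NC_pr = KL(p_ct || q)` for the composition implied by the per-cell
#' type predictions; natural log, ratios clamped at `eps`.
#'
#' @param p_est estimated composition (simplex vector).
#' @param p_ct composition from predicted cell types (simplex vector).
#' @param q_true ground-truth composition (simplex vector).
#' @param eps clamp (default 1e-8).
#' @return list with `L_NC_est` and `L_NC_pr`.
#' @export
nc_losses <- function(p_est, p_ct, q_true, eps = 1e-8) {
  kl <- function(p, q) sum(p * log(pmax(p, eps) / pmax(q, eps)))
  list(L_NC_est = kl(as.numeric(p_est), as.numeric(q_true)),
       L_NC_pr = kl(as.numeric(p_ct), as.numeric(q_true)))
}

#' Recovery parameters for composition-guided cell-type refinement
#'
#' @param alpha recovery rate (default 2; scalar `>= 0`).
#' @param confidence_mask_threshold cells whose softmax probability for a
#'   protected type exceeds this are exempt from refinement (default 0.6).
#' @param target_types character vector of type labels subject to recovery
#'   (e.g. visually similar immune types).
#' @param protected_types types whose confident predictions are masked from
#'   the mechanism (default none; the original use case protects T cells).
#' @param rng_seed integer seed for the per-patch normal draws.
#' @return An object of class `recovery_params`.
#' @export
recovery_params <- function(alpha = 2, confidence_mask_threshold = 0.6,
                            target_types = character(), protected_types = character(),
                            rng_seed = 1L) {
  stopifnot(alpha >= 0, confidence_mask_threshold >= 0,
            confidence_mask_threshold <= 1)
  structure(list(alpha = alpha,
                 confidence_mask_threshold = confidence_mask_threshold,
                 target_types = target_types,
                 protected_types = protected_types,
                 rng_seed = as.integer(rng_seed)),
            class = "recovery_params")
}

#' Per-patch recovery logit offset
#'
#' `v_t = alpha * n_cells * (p_est_t - p_ct_t) * |phi|`: the amount added
#' to every cell's logit for target type `t`, proportional to the
#' composition deficit of that type in the patch.
#'
#' @param alpha recovery rate.
#' @param n_cells number of cells in the patch.
#' @param p_est_t,p_ct_t estimated and prediction-implied proportion of
#'   type `t`.
#' @param phi the per-patch normal draw for type `t`.
#' @return Scalar offset.
#' @export
#' @examples
#' recovery_offset(2, 10, 0.4, 0.2, 0.5) # 2
recovery_offset <- function(alpha, n_cells, p_est_t, p_ct_t, phi) {
  alpha * n_cells * (p_est_t - p_ct_t) * abs(phi)
}

#' Recover under-called cell types using the estimated composition
#'
#' For each target type `t` the per-patch offset
#' `v_t = alpha * n_cells * (p_est[t] - p_ct[t]) * |Phi_t|`, with
#' `Phi_t ~ Normal(p_est[t], 1)` drawn once per patch per type under the
#' fixed seed, is added to every cell's logit for `t`. The final class is
#' the argmax over the cell's current class plus the target types, so
#' cells never move to a non-target class; cells confidently predicted as
#' a protected type are exempt.
#'
#' @param logits `n x M` initial cell-type logits.
#' @param p_est estimated composition (length M).
#' @param p_ct composition of the initial hard predictions (length M).
#' @param rp a [recovery_params()].
#' @param cell_types type labels matching the logit columns.
#' @return Integer vector of revised 1-based classes.
#' @export
recover_celltypes <- function(logits, p_est, p_ct, rp, cell_types) {
  logits <- rbind(logits)
  stopifnot(length(p_est) == ncol(logits), length(p_ct) == ncol(logits))
  if (!all(rp$target_types %in% cell_types)) {
    stop("recover_celltypes: target types outside the known type set")
  }
  n <- nrow(logits)
  cur <- apply(logits, 1L, which.max)
  if (n == 0L || length(rp$target_types) == 0L) return(cur)
  t_idx <- match(rp$target_types, cell_types)
  v <- with_substream(rp$rng_seed, 71L, {
    vapply(t_idx, function(j) {
      phi <- stats::rnorm(1L, mean = p_est[j], sd = 1)
      recovery_offset(rp$alpha, n, p_est[j], p_ct[j], phi)
    }, numeric(1L))
  })
  revised <- logits
  revised[, t_idx] <- sweep(revised[, t_idx, drop = FALSE], 2L, v, "+")
  probs <- softmax_rows(logits)
  p_idx <- match(rp$protected_types, cell_types)
  exempt <- rep(FALSE, n)
  if (length(p_idx) > 0L) {
    exempt <- apply(probs[, p_idx, drop = FALSE] >
                      rp$confidence_mask_threshold, 1L, any)
  }
  out <- cur
  for (i in seq_len(n)) {
    if (exempt[i]) next
    cand <- sort(unique(c(cur[i], t_idx)))
    out[i] <- cand[which.max(revised[i, cand])]
  }
  out
}
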