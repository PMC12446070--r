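# Gene expression prediction: reference-profile regression (a softmax
# weighting over averaged cell-type profiles), a direct regression
# alternative, a multi-head cross-attention residual conditioned on the
# estimated neighborhood composition, cell-type-specific adjusted heads,
# spot aggregation, and the expression losses.

#' Initialize the cross-attention parameters
#'
#' Tokenization: the key/value sequence holds one token per gene, each a
#' learned gene-identity embedding scale-shifted by that gene's profile
#' value `S_j`; the query is a single token linearly mapped from the
#' estimated neighborhood composition. The attended token passes through a
#' per-gene output linear map producing the residual `b`.
#'
#' @param n_ct number of cell types (query input size).
#' @param n_genes gene panel size.
#' @param n_heads attention heads (default 8).
#' @param d_head per-head width (default 64).
#' @return Named list of attention parameters.
#' @export
attention_init <- function(n_ct, n_genes, n_heads = 8L, d_head = 64L) {
  d_model <- n_heads * d_head
  list(Wq = he_init(n_ct, d_model),
       G = matrix(stats::rnorm(n_genes * d_model, 0, 1 / sqrt(d_head)),
                  n_genes, d_model),
       H = matrix(stats::rnorm(n_genes * d_model, 0, 1 / sqrt(d_head)),
                  n_genes, d_model),
       Wo = he_init(d_model, n_genes),
       bo = numeric(n_genes),
       n_heads = as.integer(n_heads), d_head = as.integer(d_head))
}

#' Predict reference-profile weights
#'
#' Two fully connected layers with ReLU followed by a softmax along the
#' profile dimension, yielding per-cell weights on the simplex over the
#' `n_AvgExp` averaged reference profiles.
#'
#' @param x_nucleus embedding vector or `n x 256` matrix.
#' @param params two-layer parameters with output size `n_AvgExp`.
#' @return `n x n_AvgExp` matrix of positive weights, rows summing to 1.
#' @export
predict_weights <- function(x_nucleus, params) {
  softmax_rows(fc2_apply(x_nucleus, params))
}

#' Weighted sum of reference profiles
#'
#' `S_j = sum_k W_k R_kj`: the per-cell expression profile implied by the
#' predicted profile weights.
#'
#' @param W weight vector or `n x K` matrix on the simplex.
#' @param R a [reference_profiles()] or a `K x n_genes` matrix.
#' @return `n x n_genes` matrix.
#' @export
weighted_profile <- function(W, R) {
  if (inherits(R, "reference_profiles")) R <- R$R
  W <- rbind(W)
  if (ncol(W) != nrow(R)) stop("weighted_profile: weight length must match profile rows")
  W %*% R
}

#' Cross-attention residual conditioned on neighborhood composition
#'
#' The estimated composition forms the query; the per-cell profile vector
#' `S` forms the keys and values (via scale-shifted gene-identity
#' embeddings). Multi-head attention followed by a linear map yields a
#' per-cell residual of length `n_genes`.
#'
#' @param p_est estimated neighborhood composition of the patch (length
#'   `n_CT`).
#' @param S per-cell profile vector or `n x n_genes` matrix.
#' @param params attention parameters from [attention_init()].
#' @return `n x n_genes` residual matrix.
#' @export
attention_residual <- function(p_est, S, params) {
  S <- rbind(S)
  n <- nrow(S)
  q <- matrix(p_est, nrow = 1L) %*% params$Wq
  outs <- vector("list", params$n_heads)
  for (h in seq_len(params$n_heads)) {
    idx <- ((h - 1L) * params$d_head + 1L):(h * params$d_head)
    qh <- q[, idx, drop = FALSE]
    Gh <- params$G[, idx, drop = FALSE]
    Hh <- params$H[, idx, drop = FALSE]
    u <- as.numeric(qh %*% t(Gh))   # per-gene key response to the query
    w0 <- as.numeric(qh %*% t(Hh))
    scores <- (sweep(S, 2L, u, "*") +
                 matrix(w0, n, length(w0), byrow = TRUE)) / sqrt(params$d_head)
    a <- softmax_rows(scores)
    outs[[h]] <- (a * S) %*% Gh + a %*% Hh
  }
  attended <- do.call(cbind, outs)
  sweep(attended %*% params$Wo, 2L, params$bo, "+")
}

#' Finalize the predicted expression
#'
#' Reference mode: `y' = ReLU(S + b)`; direct mode (no reference input):
#' `y' = ReLU(b)` with `S` feeding only the attention.
#'
#' @param S profile matrix (`n x n_genes`).
#' @param b attention residual (`n x n_genes`).
#' @param mode `"reference"` or `"direct"`.
#' @return Non-negative `n x n_genes` matrix.
#' @export
finalize_expression <- function(S, b, mode = c("reference", "direct")) {
  mode <- match.arg(mode)
  S <- rbind(S); b <- rbind(b)
  stopifnot(all(dim(S) == dim(b)))
  if (mode == "reference") pmax(S + b, 0) else pmax(b, 0)
}

#' Cell-type-specific adjusted expression loss
#'
#' Mean squared error restricted to cells whose true type is `t`; zero
#' when the batch contains no such cell. At inference, cells recovered to
#' type `t` take their expression from this head.
#'
#' @param y_adj `n x n_genes` predictions of the type-`t` head.
#' @param y_true `n x n_genes` ground-truth expression.
#' @param types true type labels per cell.
#' @param t the type this head serves.
#' @return Scalar loss.
#' @export
adjusted_expression_loss <- function(y_adj, y_true, types, t) {
  y_adj <- rbind(y_adj); y_true <- rbind(y_true)
  stopifnot(all(dim(y_adj) == dim(y_true)), length(types) == nrow(y_adj))
  sel <- types == t
  if (!any(sel)) return(0)
  mean((y_adj[sel, , drop = FALSE] - y_true[sel, , drop = FALSE])^2)
}

#' Aggregate per-cell predictions into spot-level predictions
#'
#' Elementwise sum of the predicted expression of all nuclei belonging to
#' each spot patch (weakly supervised spot mode). Spots without cells get
#' a zero vector.
#'
#' @param y_prime `n x n_genes` per-cell predictions.
#' @param membership spot identifier per cell (length n).
#' @param spots optional full set of spot identifiers (default: those
#'   present in `membership`).
#' @return `n_spots x n_genes` matrix with spot identifiers as row names.
#' @export
spot_aggregate <- function(y_prime, membership, spots = NULL) {
  y_prime <- rbind(y_prime)
  if (is.null(spots)) spots <- sort(unique(membership))
  out <- matrix(0, length(spots), ncol(y_prime),
                dimnames = list(as.character(spots), colnames(y_prime)))
  if (nrow(y_prime) > 0L) {
    agg <- rowsum(y_prime, group = as.character(membership))
    out[rownames(agg), ] <- agg
  }
  out
}

#' Expression training loss
#'
#' Mean over cells (or spots) of the squared error, averaged over the gene
#' dimension as well.
#'
#' @param pred,truth matrices of identical shape.
#' @param mode `"single-cell"` or `"spot"` (identical arithmetic; the mode
#'   names which unit the rows represent).
#' @return Scalar loss.
#' @export
expression_loss <- function(pred, truth, mode = c("single-cell", "spot")) {
  match.arg(mode)
  pred <- rbind(pred); truth <- rbind(truth)
  stopifnot(all(dim(pred) == dim(truth)))
  mean((pred - truth)^2)
}
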