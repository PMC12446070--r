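# Per-nucleus morphology embeddings: mask-pooled first/last backbone
# feature volumes, area-normalized, concatenated with the patch-level mean
# feature vector and passed through two fully connected layers.

# two-layer perceptron parameters
fc2_init <- function(d_in, d_hidden, d_out) {
  list(W1 = he_init(d_in, d_hidden), b1 = numeric(d_hidden),
       W2 = he_init(d_hidden, d_out), b2 = numeric(d_out))
}

fc2_apply <- function(x, p) {
  x <- rbind(x) # promote vectors to 1-row matrices
  h <- pmax(sweep(x %*% p$W1, 2L, p$b1, "+"), 0)
  sweep(h %*% p$W2, 2L, p$b2, "+")
}

# linear pixel indices (1-based into the H x W plane) for each valid nucleus
nucleus_pixels <- function(map, ids = map$valid_ids) {
  lab <- map$labels
  lapply(ids, function(id) which(lab == id))
}

#' Mask-pool backbone features over nuclei
#'
#' Multiplies each nucleus mask elementwise into the first and last
#' backbone feature volumes, concatenates along channels, sums over pixels
#' and divides by the nucleus pixel area (countering nucleus-size
#' variability). Under the default backbone widths the pooled vector has
#' 384 dimensions (64 + 5 x 64).
#'
#' @param seg backbone output from [forward_backbone()] (uses
#'   `first_features` and `last_features`).
#' @param map an [instance_map()]; pooling runs over `valid_ids`.
#' @return Matrix `n_nuclei x (base_width + levels*skip_width)`; rows in
#'   `valid_ids` order.
#' @export
pool_nucleus_features <- function(seg, map) {
  stopifnot(inherits(map, "instance_map"))
  if (length(map$valid_ids) == 0L) stop("pool_nucleus_features: no valid nuclei")
  present <- unique(map$labels[map$labels > 0L])
  if (!all(map$valid_ids %in% present)) {
    stop("pool_nucleus_features: nucleus id absent from map")
  }
  d1 <- dim(seg$first_features); d2 <- dim(seg$last_features)
  np <- d1[1] * d1[2]
  feat <- cbind(matrix(seg$first_features, np, d1[3]),
                matrix(seg$last_features, np, d2[3]))
  pix <- nucleus_pixels(map)
  out <- matrix(0, length(pix), ncol(feat))
  for (i in seq_along(pix)) {
    out[i, ] <- colSums(feat[pix[[i]], , drop = FALSE]) / length(pix[[i]])
  }
  rownames(out) <- map$valid_ids
  out
}

#' Patch-level feature vector
#'
#' Spatial mean of the first and last backbone feature volumes,
#' concatenated along channels.
#'
#' @param seg backbone output from [forward_backbone()].
#' @return Numeric vector of length `base_width + levels*skip_width`.
#' @export
patch_feature_vector <- function(seg) {
  d1 <- dim(seg$first_features); d2 <- dim(seg$last_features)
  c(colMeans(matrix(seg$first_features, d1[1] * d1[2], d1[3])),
    colMeans(matrix(seg$last_features, d2[1] * d2[2], d2[3])))
}

#' Embed a nucleus into the final morphology feature vector
#'
#' Concatenates the pooled per-nucleus vector with its patch-level vector
#' and applies two fully connected layers with a ReLU in between,
#' producing the 256-dimensional embedding consumed by every prediction
#' head.
#'
#' @param pooled per-nucleus pooled vector(s): vector or `n x F` matrix.
#' @param patch_vec patch-level feature vector of the same length `F`.
#' @param params two-layer parameters (`W1`, `b1`, `W2`, `b2`), e.g. from
#'   `fc2_init(2 * F, 256, 256)`.
#' @return `n x 256` embedding matrix (one row per nucleus).
#' @export
embed_nucleus <- function(pooled, patch_vec, params) {
  pooled <- rbind(pooled)
  if (ncol(pooled) != length(patch_vec)) {
    stop("embed_nucleus: pooled and patch vector lengths differ")
  }
  z <- cbind(pooled, matrix(patch_vec, nrow(pooled), length(patch_vec), byrow = TRUE))
  fc2_apply(z, params)
}
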