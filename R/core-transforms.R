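# Expression and image normalization transforms shared across modules.

#' Log-normalize an expression matrix
#'
#' Applies natural-log(1 + value) elementwise to raw counts and flips the
#' scale flag. Library-size scaling is deliberately not applied by default;
#' supply `transform` for alternative recipes (it must map the non-negative
#' raw matrix to a non-negative matrix of the same shape).
#'
#' @param expr an [expression_matrix()] with `scale = "raw_counts"`.
#' @param transform optional function replacing the default `log1p`.
#' @return An [expression_matrix()] with `scale = "log_normalized"`, gene
#'   order preserved.
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(0, 1, 3, 7), 2, 2,
#'                               dimnames = list(NULL, c("g1", "g2"))))
#' log_normalize(m)$values
log_normalize <- function(expr, transform = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$scale != "raw_counts") {
    stop("log_normalize: input must be on the raw_counts scale")
  }
  if (any(expr$values < 0)) stop("log_normalize: negative input entries")
  f <- transform %||% log1p
  v <- f(expr$values)
  expression_matrix(v, gene_names = expr$gene_names, scale = "log_normalized")
}

#' Undo the default log normalization
#'
#' `expm1` inverse of [log_normalize()]; round-trips raw counts within 1e-9.
#'
#' @param expr an [expression_matrix()] with `scale = "log_normalized"`.
#' @return An [expression_matrix()] on the raw-counts scale.
#' @export
unlog_normalize <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$scale != "log_normalized") {
    stop("unlog_normalize: input must be log_normalized")
  }
  expression_matrix(expm1(expr$values), gene_names = expr$gene_names,
                    scale = "raw_counts")
}

#' Standardize an H&E patch with per-channel statistics
#'
#' Subtracts the channel mean and divides by the channel standard deviation
#' of the training patches (stored with the model checkpoint), producing the
#' real-valued grid fed to the backbone.
#'
#' @param patch an [he_patch()].
#' @param channel_mean,channel_std numeric length-3 vectors; `channel_std`
#'   entries must be positive.
#' @return A numeric `h x w x 3` array.
#' @export
#' @examples
#' p <- he_patch(array(200, dim = c(4, 4, 3)), mpp = 0.5)
#' standardize_patch(p, c(100, 100, 100), c(50, 50, 50))[1, 1, ]
standardize_patch <- function(patch, channel_mean, channel_std) {
  stopifnot(inherits(patch, "he_patch"))
  stopifnot(length(channel_mean) == 3L, length(channel_std) == 3L)
  if (any(channel_std <= 0)) stop("standardize_patch: channel std must be positive")
  out <- patch$pixels
  for (c in 1:3) out[, , c] <- (out[, , c] - channel_mean[c]) / channel_std[c]
  out
}

#' Per-channel mean and standard deviation of a set of patches
#'
#' @param patches list of [he_patch()] objects.
#' @return list with numeric length-3 `mean` and `sd`.
#' @export
channel_stats <- function(patches) {
  stopifnot(length(patches) > 0L)
  acc <- lapply(1:3, function(c) unlist(lapply(patches, function(p) p$pixels[, , c])))
  list(mean = vapply(acc, mean, 1), sd = vapply(acc, stats::sd, 1))
}
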