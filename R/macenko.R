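# Macenko stain-color normalization: estimate the two dominant stain
# vectors of a patch from the extreme-angle percentiles of the optical-
# density eigenplane, express every pixel as stain concentrations, rescale
# the concentrations to the reference's high percentile, and reconstruct
# the image in the reference's stain basis.

#' Estimate the two stain vectors of an H&E image
#'
#' Converts 8-bit intensities to optical density
#' `OD = -log10((I + 1) / I0)`, discards near-transparent pixels (all
#' channels below `beta` OD), projects the remaining pixels onto the plane
#' of the top two covariance eigenvectors, and takes the directions at the
#' `angle_percentiles` of the projection angle as the extreme stain
#' vectors. Vectors are unit length with non-negative entries, ordered by
#' descending red-channel OD (hematoxylin first).
#'
#' @param pixels numeric `h x w x 3` array of 8-bit intensities.
#' @param I0 transmitted light intensity (default 240).
#' @param beta transparency threshold in OD units (default 0.15).
#' @param angle_percentiles lower/upper percentile of the projection angle
#'   (default `c(1, 99)`).
#' @return list with `stains` (3 x 2 matrix of unit stain OD vectors), `od`
#'   (n_pixels x 3 OD matrix) and `n_tissue` (pixels used for estimation),
#'   or `NULL` when fewer than 2 tissue pixels exist.
#' @export
estimate_stains <- function(pixels, I0 = 240, beta = 0.15,
                            angle_percentiles = c(1, 99)) {
  od <- -log10((matrix(pixels, ncol = 3L) + 1) / I0)
  tissue <- od[apply(od, 1L, max) >= beta, , drop = FALSE]
  if (nrow(tissue) < 2L) {
    return(NULL)
  }
  ev <- eigen(stats::cov(tissue), symmetric = TRUE)
  basis <- ev$vectors[, 1:2, drop = FALSE]
  # orient the plane so projections are mostly positive
  for (k in 1:2) if (sum(tissue %*% basis[, k]) < 0) basis[, k] <- -basis[, k]
  proj <- tissue %*% basis
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(phi, angle_percentiles / 100, names = FALSE)
  v <- vapply(qs, function(a) {
    u <- basis %*% c(cos(a), sin(a))
    u <- u * sign(sum(u))
    u / sqrt(sum(u^2))
  }, numeric(3L))
  # hematoxylin absorbs red strongly: order by descending red-channel OD
  if (v[1, 1] < v[1, 2]) v <- v[, 2:1]
  list(stains = v, od = od, n_tissue = nrow(tissue))
}

#' Macenko-normalize a patch against a reference patch
#'
#' Both patches have their stain vectors estimated with
#' [estimate_stains()]; the query's per-pixel stain concentrations (least
#' squares in OD space) are rescaled so their `conc_percentile` matches the
#' reference's, and the image is reconstructed in the reference stain
#' basis. Degenerate inputs (fewer than 2 tissue pixels, e.g. a pure-white
#' patch) are returned unchanged with attribute `macenko_skipped = TRUE`.
#'
#' @param patch,reference [he_patch()] objects (8-bit RGB).
#' @param I0,beta,angle_percentiles see [estimate_stains()].
#' @param conc_percentile percentile of stain concentration used for
#'   rescaling (default 99).
#' @return The normalized [he_patch()]; shape preserved.
#' @export
macenko_normalize <- function(patch, reference, I0 = 240, beta = 0.15,
                              angle_percentiles = c(1, 99),
                              conc_percentile = 99) {
  stopifnot(inherits(patch, "he_patch"), inherits(reference, "he_patch"))
  est <- estimate_stains(patch$pixels, I0, beta, angle_percentiles)
  est_ref <- estimate_stains(reference$pixels, I0, beta, angle_percentiles)
  if (is.null(est) || is.null(est_ref)) {
    out <- patch
    attr(out, "macenko_skipped") <- TRUE
    return(out)
  }
  conc <- function(e) t(qr.solve(e$stains, t(e$od)))         # n_px x 2
  C <- conc(est)
  C_ref <- conc(est_ref)
  p <- conc_percentile / 100
  max_c <- apply(C, 2L, stats::quantile, probs = p, names = FALSE)
  max_ref <- apply(C_ref, 2L, stats::quantile, probs = p, names = FALSE)
  scale <- ifelse(max_c > 0, max_ref / max_c, 1)
  C_adj <- sweep(C, 2L, scale, "*")
  C_adj[C_adj < 0] <- 0
  od_new <- C_adj %*% t(est_ref$stains)
  I_new <- I0 * 10^(-od_new) - 1
  d <- dim(patch$pixels)
  out_pix <- array(round(pmin(255, pmax(0, I_new))), dim = d)
  out <- he_patch(out_pix, origin = patch$origin, mpp = patch$mpp)
  attr(out, "macenko_skipped") <- FALSE
  out
}
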