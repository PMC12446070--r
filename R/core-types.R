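# Shared domain objects. Images are plain arrays wrapped in light S3
# classes; per-cell records are tibbles so they flow through dplyr verbs.

#' Construct an H&E patch
#'
#' An RGB tile cropped from a larger H&E image. Pixel values are 8-bit
#' intensities stored as numerics in `[0, 255]`; `origin` is the 0-based
#' (row, col) offset of the patch in its parent image and `mpp` the microns
#' per pixel.
#'
#' @param pixels numeric `h x w x 3` array with values in `[0, 255]`.
#' @param origin integer length-2 vector, 0-based (row, col) offset.
#' @param mpp microns per pixel, a positive scalar.
#' @return An object of class `he_patch`.
#' @export
#' @examples
#' p <- he_patch(array(128, dim = c(8, 8, 3)), mpp = 0.5)
#' dim(p$pixels)
he_patch <- function(pixels, origin = c(0L, 0L), mpp = 1) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  stopifnot(dim(pixels)[1] >= 1L, dim(pixels)[2] >= 1L)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("he_patch: pixel intensities must lie in [0, 255]")
  }
  stopifnot(length(origin) == 2L, is.numeric(mpp), mpp > 0)
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, origin = as.integer(origin), mpp = mpp),
            class = "he_patch")
}

#' @export
print.he_patch <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<he_patch> %d x %d px, origin (%d, %d), %.3g um/px\n",
              d[1], d[2], x$origin[1], x$origin[2], x$mpp))
  invisible(x)
}

#' Construct a nuclei instance label map
#'
#' An integer label image aligned to an [he_patch()]: 0 marks background and
#' each positive id one nucleus. `valid_ids` flags the nuclei that take part
#' in training or prediction (for example those that survived cross-modality
#' matching and area filtering).
#'
#' @param labels integer `h x w` matrix, 0 = background.
#' @param valid_ids integer vector of nucleus ids; defaults to all positive
#'   labels present.
#' @return An object of class `instance_map`.
#' @export
instance_map <- function(labels, valid_ids = NULL) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("instance_map: labels must be non-negative")
  ids <- sort(unique(labels[labels > 0L]))
  if (is.null(valid_ids)) valid_ids <- ids
  valid_ids <- as.integer(valid_ids)
  if (!all(valid_ids %in% ids)) stop("instance_map: valid_ids absent from labels")
  structure(list(labels = labels, valid_ids = valid_ids), class = "instance_map")
}

#' @export
print.instance_map <- function(x, ...) {
  cat(sprintf("<instance_map> %d x %d px, %d nuclei (%d valid)\n",
              nrow(x$labels), ncol(x$labels),
              length(unique(x$labels[x$labels > 0L])), length(x$valid_ids)))
  invisible(x)
}

#' Construct a per-cell record table
#'
#' A tibble with one row per cell: id, centroid (row, col), pixel area,
#' area in square microns, and optional true/predicted type and fold
#' assignment. `area_um2` is checked against `area_px * mpp^2` when `mpp`
#' is supplied.
#'
#' @param df data frame with at least columns `id`, `centroid_row`,
#'   `centroid_col`, `area_px`. Optional: `area_um2`, `type_true`,
#'   `type_pred`, `fold`, `patch`.
#' @param mpp microns per pixel used to derive `area_um2` when missing.
#' @return A tibble of class `cell_table`.
#' @export
cell_table <- function(df, mpp = NULL) {
  df <- tibble::as_tibble(df)
  req <- c("id", "centroid_row", "centroid_col", "area_px")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) stop("cell_table: missing columns ", paste(miss, collapse = ", "))
  if ("patch" %in% names(df)) {
    if (anyDuplicated(df[, c("patch", "id")])) {
      stop("cell_table: ids must be unique within a patch")
    }
  } else if (anyDuplicated(df$id)) {
    stop("cell_table: ids must be unique")
  }
  if (any(df$area_px < 1)) stop("cell_table: area_px must be >= 1")
  if (!("area_um2" %in% names(df))) {
    if (is.null(mpp)) stop("cell_table: supply area_um2 or mpp")
    df$area_um2 <- df$area_px * mpp^2
  }
  class(df) <- c("cell_table", class(df))
  df
}

#' Construct an expression matrix
#'
#' Cells x genes non-negative values with an explicit scale flag: raw
#' transcript counts or natural-log(1 + count) normalized values. Row order
#' matches the paired [cell_table()].
#'
#' @param values numeric cells x genes matrix, entries `>= 0`.
#' @param gene_names unique gene identifiers; defaults to `colnames(values)`.
#' @param scale `"raw_counts"` or `"log_normalized"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_names = colnames(values),
                              scale = c("raw_counts", "log_normalized")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(gene_names)) stop("expression_matrix: gene names required")
  if (anyDuplicated(gene_names)) stop("expression_matrix: gene names must be unique")
  if (length(gene_names) != ncol(values)) stop("expression_matrix: gene name length mismatch")
  if (any(values < 0)) stop("expression_matrix: negative entries")
  colnames(values) <- gene_names
  structure(list(values = values, gene_names = gene_names, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes (%s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a set of averaged reference expression profiles
#'
#' The optional single-cell reference input: one row per averaged cell-type
#' profile, columns ordered exactly as the panel's gene names. Profiles need
#' not match the cell types being predicted.
#'
#' @param R non-negative numeric matrix, profiles x genes.
#' @param profile_names labels for the averaged profiles; defaults to
#'   `rownames(R)`.
#' @param gene_names gene identifiers; defaults to `colnames(R)`.
#' @return An object of class `reference_profiles`.
#' @export
reference_profiles <- function(R, profile_names = rownames(R),
                               gene_names = colnames(R)) {
  R <- as.matrix(R)
  if (any(R < 0)) stop("reference_profiles: negative entries")
  if (is.null(profile_names)) profile_names <- paste0("profile", seq_len(nrow(R)))
  if (is.null(gene_names)) stop("reference_profiles: gene names required")
  rownames(R) <- profile_names
  colnames(R) <- gene_names
  structure(list(R = R, profile_names = profile_names, gene_names = gene_names),
            class = "reference_profiles")
}

#' Construct a neighborhood-composition vector
#'
#' A point on the probability simplex over cell types: the proportion of
#' each type among the cells of one patch.
#'
#' @param probs non-negative numeric vector summing to 1 (tolerance 1e-6).
#' @return An object of class `nc_vector` (a named numeric vector).
#' @export
nc_vector <- function(probs) {
  probs <- as.numeric(probs) * rep(1, length(probs))
  if (any(probs < 0)) stop("nc_vector: negative entries")
  if (abs(sum(probs) - 1) > 1e-6) stop("nc_vector: entries must sum to 1")
  structure(probs, class = "nc_vector")
}
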