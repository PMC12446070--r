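# Readers and writers for the standard on-disk formats: 8-bit RGB TIFF/PNG
# patches, integer-label TIFF instance maps, CSV / MatrixMarket expression,
# reference-profile CSV, transcript CSV and spot TSV tables.

#' Read an H&E patch from a TIFF or PNG file
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param origin,mpp patch metadata (see [he_patch()]).
#' @return An [he_patch()].
#' @export
read_he_patch <- function(path, origin = c(0L, 0L), mpp = 1) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  he_patch(round(img * 255), origin = origin, mpp = mpp)
}

#' Write an H&E patch to a TIFF or PNG file
#'
#' @param patch an [he_patch()].
#' @param path output path; extension selects the format.
#' @export
write_he_patch <- function(patch, path) {
  stopifnot(inherits(patch, "he_patch"))
  img <- patch$pixels / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Read an instance label map from a 16-bit single-channel TIFF
#'
#' @param path file path.
#' @param valid_ids optional subset of nucleus ids flagged as valid.
#' @return An [instance_map()].
#' @export
read_instance_map <- function(path, valid_ids = NULL) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  labels <- matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
  instance_map(labels, valid_ids = valid_ids)
}

#' Write an instance label map to a 16-bit single-channel TIFF
#'
#' Label ids must not exceed 65535. The round trip with
#' [read_instance_map()] is bit-exact.
#'
#' @param map an [instance_map()].
#' @param path output path.
#' @export
write_instance_map <- function(map, path) {
  stopifnot(inherits(map, "instance_map"))
  if (max(map$labels) > 65535L) stop("write_instance_map: labels exceed 16-bit range")
  tiff::writeTIFF(map$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an expression matrix from CSV (cells x genes, header = gene names)
#'
#' @param path file path.
#' @param scale scale flag of the stored values.
#' @return An [expression_matrix()].
#' @export
read_expression_csv <- function(path, scale = "raw_counts") {
  df <- utils::read.csv(path, check.names = FALSE)
  expression_matrix(as.matrix(df), gene_names = colnames(df), scale = scale)
}

#' Write an expression matrix to CSV
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression_csv <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  utils::write.csv(as.data.frame(expr$values), path, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from MatrixMarket with gene/cell sidecars
#'
#' Expects `<stem>.mtx` (cells x genes), `<stem>.genes.txt` and
#' `<stem>.cells.txt`.
#'
#' @param stem path without extension.
#' @param scale scale flag of the stored values.
#' @return list with the [expression_matrix()] and the cell id vector.
#' @export
read_expression_mtx <- function(stem, scale = "raw_counts") {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  genes <- readLines(paste0(stem, ".genes.txt"))
  cells <- readLines(paste0(stem, ".cells.txt"))
  list(expr = expression_matrix(m, gene_names = genes, scale = scale),
       cell_ids = cells)
}

#' Write an expression matrix to MatrixMarket with gene/cell sidecars
#' @param expr an [expression_matrix()].
#' @param stem output path without extension.
#' @param cell_ids identifiers written to the cells sidecar.
#' @export
write_expression_mtx <- function(expr, stem, cell_ids = seq_len(nrow(expr$values))) {
  stopifnot(inherits(expr, "expression_matrix"))
  Matrix::writeMM(Matrix::Matrix(expr$values, sparse = TRUE), paste0(stem, ".mtx"))
  writeLines(expr$gene_names, paste0(stem, ".genes.txt"))
  writeLines(as.character(cell_ids), paste0(stem, ".cells.txt"))
  invisible(stem)
}

#' Read reference profiles from CSV (profile names as row labels)
#' @param path file path.
#' @return A [reference_profiles()].
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  reference_profiles(as.matrix(df))
}

#' Write reference profiles to CSV
#' @param ref a [reference_profiles()].
#' @param path output path.
#' @export
write_reference_csv <- function(ref, path) {
  stopifnot(inherits(ref, "reference_profiles"))
  utils::write.csv(as.data.frame(ref$R), path, row.names = TRUE)
  invisible(path)
}

#' Read a transcript table from CSV
#'
#' Columns `gene`, `x`, `y`, `qv` (phred-scaled quality value) at minimum.
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_transcripts_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Read a spot table from TSV
#'
#' Columns `spot_id`, `center_row`, `center_col`, then one column per gene.
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_spot_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Write a spot table to TSV
#' @param spots tibble as returned by [read_spot_table()].
#' @param path output path.
#' @export
write_spot_table <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
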