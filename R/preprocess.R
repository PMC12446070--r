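# Data preparation: transcript QC, cross-modality nucleus matching, cell
# filtering, tiling, cross-validation splits, and spot-mode patch / gene
# preparation. Macenko stain normalization lives in macenko.R.

#' Filter low-quality and control transcripts
#'
#' Removes transcripts with a phred-scaled quality value below `qv_min`
#' (a qv exactly at the threshold is retained) and transcripts whose gene
#' name matches any of the configured control prefixes (negative controls,
#' blanks, antisense probes).
#'
#' @param transcripts data frame with at least columns `gene` and `qv`.
#' @param qv_min minimum retained quality value (default 20).
#' @param control_prefixes character vector of gene-name prefixes flagged as
#'   control probes (case-insensitive).
#' @return The filtered transcript tibble.
#' @export
filter_transcripts <- function(transcripts,
                               qv_min = 20,
                               control_prefixes = c("NegControl", "BLANK",
                                                    "Blank", "antisense",
                                                    "DeprecatedCodeword")) {
  transcripts <- tibble::as_tibble(transcripts)
  miss <- setdiff(c("gene", "qv"), names(transcripts))
  if (length(miss) > 0L) {
    stop("filter_transcripts: missing columns ", paste(miss, collapse = ", "))
  }
  if (nrow(transcripts) == 0L) return(transcripts)
  pat <- paste0("^(", paste(control_prefixes, collapse = "|"), ")")
  dplyr::filter(transcripts,
                .data$qv >= qv_min,
                !grepl(pat, .data$gene, ignore.case = TRUE))
}

#' Match H&E nuclei to cells/nuclei segmented from spatial data
#'
#' For every H&E nucleus the candidate is the spatial-transcriptomics object
#' with maximal pixel overlap; the pair is kept iff that overlap covers at
#' least `min_overlap` of the H&E nucleus area (inclusive). Ties on overlap
#' are broken toward the smaller spatial label id. Each H&E nucleus maps to
#' at most one object.
#'
#' @param he_map,sst_map [instance_map()] objects of identical shape, in the
#'   same registered pixel grid.
#' @param min_overlap minimum overlap fraction of the H&E nucleus area
#'   (default 0.5).
#' @return A tibble with columns `he_id`, `sst_id`, `overlap_px`,
#'   `overlap_fraction`.
#' @export
match_nuclei <- function(he_map, sst_map, min_overlap = 0.5) {
  stopifnot(inherits(he_map, "instance_map"), inherits(sst_map, "instance_map"))
  if (!identical(dim(he_map$labels), dim(sst_map$labels))) {
    stop("match_nuclei: maps must share the same shape")
  }
  ov <- cpp_label_overlap(he_map$labels, sst_map$labels)
  he_ids <- sort(unique(he_map$labels[he_map$labels > 0L]))
  if (length(he_ids) == 0L || nrow(ov) == 0L) {
    return(tibble::tibble(he_id = integer(), sst_id = integer(),
                          overlap_px = integer(), overlap_fraction = numeric()))
  }
  areas <- tabulate(he_map$labels[he_map$labels > 0L])
  tibble::tibble(he_id = ov[, 1], sst_id = ov[, 2], overlap_px = ov[, 3]) |>
    dplyr::arrange(.data$he_id, dplyr::desc(.data$overlap_px), .data$sst_id) |>
    dplyr::distinct(.data$he_id, .keep_all = TRUE) |>
    dplyr::mutate(overlap_fraction = .data$overlap_px / areas[.data$he_id]) |>
    dplyr::filter(.data$overlap_fraction >= min_overlap)
}

#' Filter cells by expression, annotation and nucleus area
#'
#' Drops cells with zero total expression count, cells typed `"unassigned"`,
#' and cells whose nucleus area is strictly below `min_area_um2` square
#' microns. The expression matrix rows are kept aligned.
#'
#' @param cells a [cell_table()].
#' @param expr an [expression_matrix()] with rows aligned to `cells`.
#' @param min_area_um2 area threshold (default 10); strictly smaller nuclei
#'   are removed.
#' @return list with the filtered `cells` and `expr`.
#' @export
filter_cells <- function(cells, expr, min_area_um2 = 10) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (nrow(cells) != nrow(expr$values)) {
    stop("filter_cells: cells and expression rows are misaligned")
  }
  keep <- rowSums(expr$values) > 0 & cells$area_um2 >= min_area_um2
  if ("type_true" %in% names(cells)) {
    keep <- keep & !(!is.na(cells$type_true) & cells$type_true == "unassigned")
  }
  list(cells = cells[keep, , drop = FALSE],
       expr = expression_matrix(expr$values[keep, , drop = FALSE],
                                gene_names = expr$gene_names,
                                scale = expr$scale))
}

#' Tile an image extent into patches
#'
#' Origins advance on a stride of `size - overlap`; the final row/column
#' origin is clamped so the last patch ends exactly at the image border
#' (no synthetic padding). Every pixel is covered at least once.
#'
#' @param image_extent length-2 (height, width) in pixels.
#' @param size patch side length.
#' @param overlap overlap between successive patches, `0 <= overlap < size`.
#' @return A tibble of 0-based patch origins (`row0`, `col0`), in scan
#'   order (rows advancing fastest within a column of tiles).
#' @export
#' @examples
#' tile_patches(c(512, 512), 256, 0)
tile_patches <- function(image_extent, size, overlap = 0L) {
  stopifnot(length(image_extent) == 2L, size > overlap, overlap >= 0L)
  H <- image_extent[1]; W <- image_extent[2]
  if (size > H || size > W) {
    stop("tile_patches: patch size exceeds the image extent")
  }
  axis_origins <- function(n) {
    if (size >= n) return(0L)
    stride <- size - overlap
    o <- seq.int(0L, n - size, by = stride)
    if (o[length(o)] + size < n) o <- c(o, n - size)
    as.integer(o)
  }
  g <- expand.grid(row0 = axis_origins(H), col0 = axis_origins(W))
  tibble::tibble(row0 = g$row0, col0 = g$col0)
}

#' Horizontal cross-validation bands over an image
#'
#' Sections the image into `k` near-equal horizontal bands; fold `f` tests
#' on band `f`, validates on a strip of height `floor(H / 10)` (at least 1)
#' taken from the top of the remaining region, and trains on the rest. Rows
#' are 0-based half-open ranges `[start, end)`.
#'
#' @param image_extent length-2 (height, width).
#' @param k number of folds (`>= 2`).
#' @return A tibble with one row per fold and role: columns `fold`, `role`
#'   (`train` rows may span two disjoint ranges and then occupy two rows),
#'   `row_start`, `row_end`.
#' @export
make_cv_splits <- function(image_extent, k = 5L) {
  H <- image_extent[1]
  stopifnot(k >= 2L, H >= k)
  bounds <- round(seq(0, H, length.out = k + 1))
  val_h <- max(1L, floor(H / 10))
  out <- list()
  for (f in seq_len(k)) {
    t0 <- bounds[f]; t1 <- bounds[f + 1]
    # remaining region, as up to two disjoint row ranges
    rem <- list()
    if (t0 > 0) rem <- c(rem, list(c(0, t0)))
    if (t1 < H) rem <- c(rem, list(c(t1, H)))
    # validation strip from the top of the remaining region
    v <- rem[[1]]
    vh <- min(val_h, v[2] - v[1])
    val <- c(v[1], v[1] + vh)
    rem[[1]] <- c(val[2], v[2])
    rem <- Filter(function(r) r[2] > r[1], rem)
    rows <- list(tibble::tibble(fold = f, role = "test", row_start = t0, row_end = t1),
                 tibble::tibble(fold = f, role = "val", row_start = val[1], row_end = val[2]))
    for (r in rem) {
      rows <- c(rows, list(tibble::tibble(fold = f, role = "train",
                                          row_start = r[1], row_end = r[2])))
    }
    out[[f]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}

# bilinear resize of an h x w x c array to (out_h, out_w)
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  # align centers: sample at positions mapping output pixel centers to input
  ry <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  rx <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(ry), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(rx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ry - y0, 0), 1); fx <- pmin(pmax(rx - x0, 0), 1)
  out <- array(0, dim = c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) {
    m <- img[, , c]
    a <- m[y0, x0] * (1 - fy) + m[y1, x0] * fy
    b <- m[y0, x1] * (1 - fy) + m[y1, x1] * fy
    out[, , c] <- a * matrix(1 - fx, out_h, out_w, byrow = TRUE) +
      b * matrix(fx, out_h, out_w, byrow = TRUE)
  }
  out
}

reflect_index <- function(i, n) {
  # reflect out-of-range 1-based indices back into [1, n]
  p <- 2L * n - 2L
  if (p <= 0L) return(rep(1L, length(i)))
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

#' Extract spot-centered patches for spot-level prediction
#'
#' Per spot: a 224 x 224 crop centered on the spot, then the central
#' 112 x 112 crop, bilinearly resized to 256 x 256 so nuclei appear at a
#' scale compatible with the single-cell setting. Spots near the border are
#' handled by reflect-padding.
#'
#' @param image numeric `H x W x 3` array (8-bit intensities).
#' @param spots data frame with columns `spot_id`, `center_row`,
#'   `center_col` (0-based pixel centers).
#' @param crop_size,center_size,out_size pixel geometry (defaults
#'   224 / 112 / 256).
#' @param mpp microns per pixel of `image`.
#' @return list of [he_patch()] objects, one per spot, in input order.
#' @export
make_spot_patches <- function(image, spots, crop_size = 224L,
                              center_size = 112L, out_size = 256L, mpp = 1) {
  d <- dim(image)
  stopifnot(length(d) == 3L)
  if (any(spots$center_row < 0 | spots$center_row >= d[1] |
          spots$center_col < 0 | spots$center_col >= d[2])) {
    stop("make_spot_patches: spot centers must lie inside the image")
  }
  half <- crop_size %/% 2L
  off <- (crop_size - center_size) %/% 2L
  lapply(seq_len(nrow(spots)), function(i) {
    cy <- round(spots$center_row[i]) + 1L
    cx <- round(spots$center_col[i]) + 1L
    ys <- reflect_index((cy - half):(cy + half - 1L), d[1])
    xs <- reflect_index((cx - half):(cx + half - 1L), d[2])
    crop <- image[ys, xs, , drop = FALSE]
    centre <- crop[(off + 1L):(off + center_size),
                   (off + 1L):(off + center_size), , drop = FALSE]
    pix <- round(pmin(pmax(resize_bilinear(centre, out_size, out_size), 0), 255))
    he_patch(pix, origin = c(0L, 0L), mpp = mpp * center_size / out_size)
  })
}

#' Select genes for spot-mode training
#'
#' Takes the union over tissue sections of each section's `top_k` most
#' variable genes, then removes genes expressed (count > 0) in fewer than
#' `min_spots` spots pooled over all sections. Variability is ranked by the
#' per-gene variance of log-normalized values.
#'
#' @param spot_exprs list of spots x genes matrices (shared gene columns),
#'   one per tissue section.
#' @param top_k most-variable genes taken per section (capped at the panel
#'   size).
#' @param min_spots minimum number of expressing spots across all sections.
#' @return Character vector of selected gene names, in panel order.
#' @export
select_spot_genes <- function(spot_exprs, top_k = 1000L, min_spots = 1000L) {
  stopifnot(length(spot_exprs) >= 1L)
  genes <- colnames(spot_exprs[[1]])
  top_k <- min(top_k, length(genes))
  top_union <- unique(unlist(lapply(spot_exprs, function(m) {
    v <- apply(log1p(m), 2L, stats::var)
    colnames(m)[order(v, decreasing = TRUE)[seq_len(top_k)]]
  })))
  n_expressing <- Reduce(`+`, lapply(spot_exprs, function(m) colSums(m > 0)))
  keep <- names(n_expressing)[n_expressing >= min_spots]
  genes[genes %in% intersect(top_union, keep)]
}
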