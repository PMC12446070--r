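# Whole-image inference: overlapping tiling, unique nucleus-to-tile
# assignment, per-tile forward passes, composition-guided recovery,
# checkpoint ensembling and knowledge injection.

#' Inference configuration
#'
#' @param tile_size tile edge in pixels (default 256); clamped to the
#'   image extent when the image is smaller than a tile.
#' @param tile_overlap overlap between adjacent tiles in pixels (default
#'   30, i.e. stride `tile_size - tile_overlap`).
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(tile_size = 256L, tile_overlap = 30L) {
  stopifnot(tile_size >= 1L, tile_overlap >= 0L, tile_overlap < tile_size)
  structure(list(tile_size = as.integer(tile_size),
                 tile_overlap = as.integer(tile_overlap)),
            class = "inference_config")
}

#' Assign each nucleus to the tile holding most of its area
#'
#' With overlapping tiles a nucleus can fall into several tiles; it is
#' predicted exactly once, in the tile containing the largest number of
#' its pixels (ties go to the earliest tile in scan order).
#'
#' @param map an [instance_map()] covering the full image.
#' @param tiles tibble of 0-based tile origins from [tile_patches()].
#' @param size tile edge in pixels.
#' @return Integer vector: for each of `map$valid_ids`, the 1-based row
#'   index into `tiles`.
#' @export
assign_nuclei_to_tiles <- function(map, tiles, size) {
  ids <- map$valid_ids
  best_tile <- integer(length(ids))
  best_area <- integer(length(ids))
  for (k in seq_len(nrow(tiles))) {
    sub <- map$labels[tiles$row0[k] + seq_len(size),
                      tiles$col0[k] + seq_len(size), drop = FALSE]
    cnt <- tabulate(match(sub, ids), nbins = length(ids))
    better <- cnt > best_area
    best_area[better] <- cnt[better]
    best_tile[better] <- k
  }
  if (any(best_area == 0L)) {
    stop("assign_nuclei_to_tiles: a nucleus has no pixels in any tile")
  }
  best_tile
}

crop_he <- function(patch, r0, c0, size) {
  he_patch(patch$pixels[r0 + seq_len(size), c0 + seq_len(size), , drop = FALSE],
           origin = patch$origin + c(r0, c0), mpp = patch$mpp)
}

# per-tile raw forward pass over the whole image; shared by single-model
# and ensemble prediction. Returns one record per non-empty tile.
predict_image_raw <- function(model, image, map, cfg) {
  d <- dim(map$labels)
  size <- min(cfg$tile_size, d)
  overlap <- min(cfg$tile_overlap, size - 1L)
  tiles <- tile_patches(d, size = size, overlap = overlap)
  owner <- assign_nuclei_to_tiles(map, tiles, size)
  out <- vector("list", nrow(tiles))
  for (k in seq_len(nrow(tiles))) {
    ids <- map$valid_ids[owner == k]
    if (length(ids) == 0L) next
    sub_lab <- map$labels[tiles$row0[k] + seq_len(size),
                          tiles$col0[k] + seq_len(size), drop = FALSE]
    sub_lab[!(sub_lab %in% ids)] <- 0L
    tmap <- instance_map(sub_lab, valid_ids = ids)
    tpatch <- crop_he(image, tiles$row0[k], tiles$col0[k], size)
    fw <- hx_forward_patch(model, tpatch, tmap)
    out[[k]] <- list(tile = k, ids = ids, ct_probs = fw$ct_probs,
                     p_est = fw$p_est, y_prime = fw$y_prime, y_adj = fw$y_adj)
  }
  out[!vapply(out, is.null, TRUE)]
}

# turn averaged per-tile raw outputs into final calls; recovery operates
# per tile with the hard predicted composition as p_ct
finalize_tiles <- function(raws, model, recovery) {
  cfg <- model$config
  M <- length(cfg$cell_types)
  rows <- list()
  exprs <- list()
  for (rt in raws) {
    logits <- log(pmax(rt$ct_probs, 1e-12))
    cur <- apply(logits, 1L, which.max)
    cls <- cur
    if (!is.null(recovery)) {
      p_ct <- tabulate(cur, nbins = M) / length(cur)
      zero <- recovery$zero_types %||% character()
      if (length(zero) > 0L) p_ct[match(zero, cfg$cell_types)] <- 0
      cls <- recover_celltypes(logits, rt$p_est, p_ct, recovery, cfg$cell_types)
    }
    y <- rt$y_prime
    for (i in seq_along(cls)) {
      t <- cfg$cell_types[cls[i]]
      if (cls[i] != cur[i] && t %in% names(rt$y_adj)) {
        y[i, ] <- rt$y_adj[[t]][i, ]
      }
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = rt$ids, tile = rt$tile,
      type_pred = cfg$cell_types[cls],
      recovered = cls != cur,
      confidence = rt$ct_probs[cbind(seq_along(cls), cls)])
    rownames(y) <- rt$ids
    exprs[[length(exprs) + 1L]] <- y
  }
  cells <- dplyr::arrange(dplyr::bind_rows(rows), .data$id)
  y_all <- do.call(rbind, exprs)[as.character(cells$id), , drop = FALSE]
  colnames(y_all) <- cfg$gene_names
  structure(list(cells = cells,
                 expression = expression_matrix(y_all, cfg$gene_names,
                                                scale = "log_normalized"),
                 p_est = lapply(raws, `[[`, "p_est"),
                 composition = tabulate(match(cells$type_pred, cfg$cell_types),
                                        nbins = M) / nrow(cells)),
            class = "hx_prediction")
}

#' @export
print.hx_prediction <- function(x, ...) {
  cat(sprintf("<hx_prediction> %d cells, %d genes, %d recovered\n",
              nrow(x$cells), ncol(x$expression$values), sum(x$cells$recovered)))
  invisible(x)
}

#' Predict cell types and expression over a whole image
#'
#' Tiles the image with overlap, predicts each nucleus exactly once in the
#' tile holding most of its area, optionally applies composition-guided
#' recovery per tile (the hard composition of the tile's initial
#' predictions serves as the prediction-implied composition), and takes
#' the expression of cells recovered to a target type from that type's
#' adjusted head.
#'
#' @param model a trained `hx_model` (or an `hx_fit`; its selected model
#'   is used).
#' @param image full [he_patch()].
#' @param map full [instance_map()]; `valid_ids` defines the predicted
#'   nuclei.
#' @param cfg an [inference_config()].
#' @param recovery optional [recovery_params()]; `NULL` disables recovery.
#' @return An `hx_prediction`: `cells` (tibble with `id`, `tile`,
#'   `type_pred`, `recovered`, `confidence`), `expression`
#'   (log-normalized [expression_matrix()] with ids as row names) and the
#'   predicted `composition`.
#' @export
predict_image <- function(model, image, map, cfg = inference_config(),
                          recovery = NULL) {
  if (inherits(model, "hx_fit")) model <- model$model
  raws <- predict_image_raw(model, image, map, cfg)
  if (length(raws) == 0L) stop("predict_image: no valid nuclei to predict")
  finalize_tiles(raws, model, recovery)
}

#' Ensemble prediction over several checkpoints
#'
#' Averages post-softmax cell-type probabilities and predicted expression
#' across models before any argmax or recovery, then finalizes exactly as
#' [predict_image()]. All models must share the gene panel and cell-type
#' set.
#'
#' @param models list of `hx_model`/`hx_fit` objects.
#' @inheritParams predict_image
#' @return An `hx_prediction`.
#' @export
ensemble_predict <- function(models, image, map, cfg = inference_config(),
                             recovery = NULL) {
  stopifnot(length(models) >= 1L)
  models <- lapply(models, function(m) if (inherits(m, "hx_fit")) m$model else m)
  ref <- models[[1L]]$config
  for (m in models[-1L]) {
    if (!identical(m$config$gene_names, ref$gene_names) ||
        !identical(m$config$cell_types, ref$cell_types)) {
      stop("ensemble_predict: models disagree on gene panel or cell types")
    }
  }
  raw_sets <- lapply(models, predict_image_raw, image = image, map = map, cfg = cfg)
  if (length(raw_sets[[1L]]) == 0L) stop("ensemble_predict: no valid nuclei to predict")
  avg <- raw_sets[[1L]]
  for (s in raw_sets[-1L]) {
    for (k in seq_along(avg)) {
      avg[[k]]$ct_probs <- avg[[k]]$ct_probs + s[[k]]$ct_probs
      avg[[k]]$p_est <- avg[[k]]$p_est + s[[k]]$p_est
      avg[[k]]$y_prime <- avg[[k]]$y_prime + s[[k]]$y_prime
      for (t in names(avg[[k]]$y_adj)) {
        avg[[k]]$y_adj[[t]] <- avg[[k]]$y_adj[[t]] + s[[k]]$y_adj[[t]]
      }
    }
  }
  nm <- length(models)
  for (k in seq_along(avg)) {
    avg[[k]]$ct_probs <- avg[[k]]$ct_probs / nm
    avg[[k]]$p_est <- avg[[k]]$p_est / nm
    avg[[k]]$y_prime <- avg[[k]]$y_prime / nm
    avg[[k]]$y_adj <- lapply(avg[[k]]$y_adj, `/`, nm)
  }
  finalize_tiles(avg, models[[1L]], recovery)
}

#' Knowledge-injection recovery settings
#'
#' Converts recovery parameters to the knowledge-injection regime: a very
#' large recovery rate so the composition estimate dominates, and the
#' prediction-implied composition forced to zero for the listed types
#' (used when the classifier never proposes a type, such as visually
#' distinctive malignant cells absent from training).
#'
#' @param rp a [recovery_params()].
#' @param alpha injection recovery rate (default 10000).
#' @param zero_types types whose prediction-implied composition is set to
#'   0 during recovery; defaults to the recovery target types.
#' @return Modified `recovery_params` carrying a `zero_types` field.
#' @export
knowledge_injection <- function(rp, alpha = 10000, zero_types = rp$target_types) {
  stopifnot(inherits(rp, "recovery_params"))
  rp$alpha <- alpha
  rp$zero_types <- zero_types
  rp
}
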