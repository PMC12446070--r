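# Total-loss assembly, dihedral augmentation, the AdamW optimization loop
# and rank-based checkpoint selection.

#' Training configuration
#'
#' Defaults mirror the reference training recipe: 50 epochs, batch size 8,
#' AdamW at a fixed learning rate of 0.001 with first/second moment
#' estimates 0.9/0.999 and weight decay 0.0001, the embedding consistency
#' loss scaled by 100, and flip/right-angle-rotation augmentation.
#'
#' @param epochs,batch_size,lr,beta1,beta2,weight_decay optimizer settings.
#' @param embed_loss_scale multiplier on the embedding consistency loss.
#' @param seed integer seed controlling sample order and augmentation.
#' @param augmentation logical; random flips and 90/180/270-degree
#'   rotations applied on the fly.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 8L, lr = 0.001,
                         beta1 = 0.9, beta2 = 0.999, weight_decay = 0.0001,
                         embed_loss_scale = 100, seed = 1L,
                         augmentation = TRUE) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, beta1 > 0, beta2 > 0,
            weight_decay >= 0, embed_loss_scale > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay,
                 embed_loss_scale = embed_loss_scale,
                 seed = as.integer(seed), augmentation = isTRUE(augmentation)),
            class = "train_config")
}

#' Assemble the total multitask loss
#'
#' Sum of the nine loss components with the stated scalings: the embedding
#' consistency loss is scaled by `embed_scale` (default 100) and the
#' adjusted expression loss inversely by `n_ct_aux`, the number of cell
#' types in the auxiliary prediction; all other components enter
#' unweighted.
#'
#' @param components named list or vector with entries `L_Morph`,
#'   `L_CT_class`, `L_CT_embed`, `L_CT_logits`, `L_CT_expr`, `L_NC_est`,
#'   `L_NC_pr`, `L_GE_adj`, `L_GE`.
#' @param n_ct_aux number of auxiliary cell types (`>= 1`).
#' @param embed_scale multiplier on `L_CT_embed` (default 100).
#' @return Scalar total loss.
#' @export
#' @examples
#' comp <- as.list(stats::setNames(rep(1, 9),
#'   c("L_Morph", "L_CT_class", "L_CT_embed", "L_CT_logits", "L_CT_expr",
#'     "L_NC_est", "L_NC_pr", "L_GE_adj", "L_GE")))
#' total_loss(comp, n_ct_aux = 5) # 107.2
total_loss <- function(components, n_ct_aux, embed_scale = 100) {
  stopifnot(n_ct_aux >= 1)
  req <- c("L_Morph", "L_CT_class", "L_CT_embed", "L_CT_logits", "L_CT_expr",
           "L_NC_est", "L_NC_pr", "L_GE_adj", "L_GE")
  components <- as.list(components)
  miss <- setdiff(req, names(components))
  if (length(miss) > 0L) {
    stop("total_loss: missing components ", paste(miss, collapse = ", "))
  }
  v <- vapply(components[req], as.numeric, numeric(1))
  sum(v * c(1, 1, embed_scale, 1, 1, 1, 1, 1 / n_ct_aux, 1))
}

# dihedral transforms on matrices / h x w x c arrays
apply_dihedral <- function(x, code) {
  f <- function(m) {
    switch(code,
           identity = m,
           hflip = m[, rev(seq_len(ncol(m))), drop = FALSE],
           vflip = m[rev(seq_len(nrow(m))), , drop = FALSE],
           rot90 = t(m)[rev(seq_len(ncol(m))), , drop = FALSE],
           rot180 = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
           rot270 = t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
           stop("unknown transform"))
  }
  if (is.matrix(x)) return(f(x))
  d <- dim(x)
  slices <- lapply(seq_len(d[3]), function(c) f(x[, , c]))
  out <- array(0, dim = c(dim(slices[[1]]), d[3]))
  for (c in seq_len(d[3])) out[, , c] <- slices[[c]]
  out
}

#' Randomly augment a patch and its aligned label maps
#'
#' Draws one of identity, horizontal flip, vertical flip, or rotation by
#' 90, 180 or 270 degrees, and applies the identical spatial transform to
#' the image and every label map, preserving nucleus pixel counts.
#'
#' @param patch numeric `h x w x c` array.
#' @param maps list of aligned matrices or arrays (instance map, target
#'   map, ...).
#' @return list with `patch`, `maps` and the chosen `transform`.
#' @export
augment <- function(patch, maps = list()) {
  codes <- c("identity", "hflip", "vflip", "rot90", "rot180", "rot270")
  code <- sample(codes, 1L)
  list(patch = apply_dihedral(patch, code),
       maps = lapply(maps, apply_dihedral, code = code),
       transform = code)
}

# ---- AdamW --------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, cfg, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps) +
      cfg$weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - cfg$lr * upd
  }
  list(params = params, state = state)
}

# ---- training data assembly --------------------------------------------

#' Assemble per-patch training items
#'
#' Pairs patches with their instance maps, rasterized type targets,
#' per-nucleus log-normalized expression and ground-truth neighborhood
#' composition. Nuclei are restricted to each map's `valid_ids` with a
#' type label and expression row.
#'
#' @param patches list of [he_patch()].
#' @param maps list of [instance_map()].
#' @param cells a [cell_table()] with columns `patch`, `id`, `type_true`
#'   and a `cell` row key into `expr`.
#' @param expr log-normalized [expression_matrix()] aligned to
#'   `cells$cell`.
#' @param cell_types ordered type labels.
#' @return list of training items consumed by [train_model()].
#' @export
prepare_items <- function(patches, maps, cells, expr, cell_types) {
  stopifnot(length(patches) == length(maps))
  if (expr$scale != "log_normalized") {
    stop("prepare_items: expression must be log-normalized")
  }
  lapply(seq_along(patches), function(i) {
    ci <- cells[cells$patch == i, , drop = FALSE]
    ci <- ci[ci$id %in% maps[[i]]$valid_ids & !is.na(ci$type_true), , drop = FALSE]
    ci <- ci[order(ci$id), , drop = FALSE]
    type_idx <- match(ci$type_true, cell_types)
    q <- tabulate(type_idx, nbins = length(cell_types))
    list(patch = patches[[i]],
         map = instance_map(maps[[i]]$labels, valid_ids = ci$id),
         cells = ci,
         type_idx = type_idx,
         y_log = expr$values[ci$cell, , drop = FALSE],
         q_true = if (nrow(ci) > 0L) q / sum(q) else NULL)
  })
}

# build the per-step graph inputs from an item (with optional augmentation)
item_tensors <- function(item, model, augmenting) {
  pix_img <- item$patch$pixels
  lab <- item$map$labels
  if (augmenting) {
    a <- augment(pix_img, list(lab))
    pix_img <- a$patch
    lab <- a$maps[[1]]
  }
  map <- instance_map(lab, valid_ids = item$map$valid_ids)
  patch <- he_patch(pix_img, mpp = item$patch$mpp)
  x_std <- standardize_patch(patch, model$channel_mean, model$channel_sd)
  target <- rasterize_types(map, item$cells, model$config$cell_types)
  list(x_std = x_std, target_map = target, pix = nucleus_pixels(map),
       type_idx = item$type_idx, y_log = item$y_log, q_true = item$q_true)
}

# ---- the optimization loop ---------------------------------------------

#' Train the multitask model
#'
#' Minimizes the total loss with AdamW at the configured
#' settings, randomizing sample order each epoch, applying on-the-fly
#' dihedral augmentation, and recording one checkpoint per epoch together
#' with validation macro-F1 (auxiliary cell-type head) and mean per-gene
#' Pearson correlation of the predicted expression. Fully reproducible
#' under the config seed.
#'
#' @param items training items from [prepare_items()]; at least one with a
#'   valid nucleus.
#' @param val_items validation items (may be empty; metrics then NA).
#' @param model an [hx_model_init()] model. Its channel statistics are
#'   computed from the training patches if unset.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress to stderr.
#' @return An object of class `hx_fit`: the trained model (parameters from
#'   the rank-selected checkpoint), `checkpoints` (per-epoch parameter
#'   lists), `metrics` (tibble: epoch, train_loss, component means,
#'   val_f1, val_pcc) and `selected_epoch`.
#' @export
train_model <- function(items, val_items = list(), model, cfg = train_config(),
                        verbose = TRUE) {
  stopifnot(length(items) >= 1L)
  if (!any(vapply(items, function(it) length(it$type_idx) > 0L, TRUE))) {
    stop("train_model: no training patch contains a valid nucleus")
  }
  if (is.null(model$channel_mean)) {
    cs <- channel_stats(lapply(items, `[[`, "patch"))
    model$channel_mean <- cs$mean
    model$channel_sd <- cs$sd
  }
  params <- model$params
  state <- adamw_init(params)
  checkpoints <- vector("list", cfg$epochs)
  metrics <- vector("list", cfg$epochs)
  with_substream(cfg$seed, 31L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(items))
      comp_sum <- NULL
      loss_sum <- 0
      nb <- 0L
      b0 <- 1L
      while (b0 <= length(ord)) {
        batch <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        b0 <- b0 + cfg$batch_size
        grads <- NULL
        for (ix in batch) {
          it <- item_tensors(items[[ix]], model, cfg$augmentation)
          pn <- lapply(params, ag_leaf)
          g <- hx_graph(model, pn, it)
          ag_backward(g$total)
          gi <- lapply(pn, function(p) p$grad)
          if (is.null(grads)) {
            grads <- gi
          } else {
            for (nm in names(grads)) {
              if (!is.null(gi[[nm]])) {
                grads[[nm]] <- if (is.null(grads[[nm]])) gi[[nm]] else grads[[nm]] + gi[[nm]]
              }
            }
          }
          loss_sum <- loss_sum + g$total$value
          comp_sum <- if (is.null(comp_sum)) g$components else comp_sum + g$components
          nb <- nb + 1L
        }
        grads <- lapply(grads, function(g) if (is.null(g)) NULL else g / length(batch))
        stepped <- adamw_step(params, grads, state, cfg)
        params <- stepped$params
        state <- stepped$state
      }
      checkpoints[[epoch]] <- params
      vm <- validate_epoch(model, params, val_items)
      metrics[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = loss_sum / nb,
        tibble::as_tibble(as.list(comp_sum / nb)),
        val_f1 = vm$f1, val_pcc = vm$pcc)
      if (verbose) {
        message(sprintf("epoch %d/%d: loss %.4f, val F1 %.3f, val PCC %.3f",
                        epoch, cfg$epochs, loss_sum / nb, vm$f1, vm$pcc))
      }
    }
  })
  metrics <- dplyr::bind_rows(metrics)
  sel <- if (all(is.na(metrics$val_f1))) {
    cfg$epochs
  } else {
    select_checkpoint(metrics$val_f1, metrics$val_pcc)
  }
  model$params <- checkpoints[[sel]]
  structure(list(model = model, checkpoints = checkpoints, metrics = metrics,
                 selected_epoch = sel, config = cfg),
            class = "hx_fit")
}

#' @export
print.hx_fit <- function(x, ...) {
  cat(sprintf("<hx_fit> %d epochs, selected epoch %d (val F1 %.3f, val PCC %.3f)\n",
              nrow(x$metrics), x$selected_epoch,
              x$metrics$val_f1[x$selected_epoch],
              x$metrics$val_pcc[x$selected_epoch]))
  invisible(x)
}

# macro F1 of the auxiliary cell-type head and mean per-gene PCC on the
# validation items, under the given parameters
validate_epoch <- function(model, params, val_items) {
  if (length(val_items) == 0L) return(list(f1 = NA_real_, pcc = NA_real_))
  preds <- truth <- integer()
  y_pred <- y_true <- list()
  for (it in val_items) {
    if (length(it$type_idx) == 0L) next
    fw <- hx_forward_patch(model, it$patch, it$map, params)
    preds <- c(preds, apply(fw$ct_logits, 1L, which.max))
    truth <- c(truth, it$type_idx)
    y_pred[[length(y_pred) + 1L]] <- fw$y_prime
    y_true[[length(y_true) + 1L]] <- it$y_log
  }
  if (length(truth) == 0L) return(list(f1 = NA_real_, pcc = NA_real_))
  cm <- celltype_metrics(model$config$cell_types[preds],
                         model$config$cell_types[truth])
  yp <- do.call(rbind, y_pred)
  yt <- do.call(rbind, y_true)
  pcc <- if (nrow(yp) >= 2L) {
    g <- per_gene_pcc(expression_matrix(pmax(yp, 0), model$config$gene_names,
                                        scale = "log_normalized"),
                      expression_matrix(yt, model$config$gene_names,
                                        scale = "log_normalized"))
    mean(g$pcc, na.rm = TRUE)
  } else NA_real_
  list(f1 = cm$macro_f1, pcc = pcc)
}

#' Select the best epoch by rank-averaging two validation metrics
#'
#' Ranks each metric across epochs (rank 1 = best, larger is better) and
#' returns the epoch minimizing the mean of the F1 and PCC ranks; ties go
#' to the earliest epoch.
#'
#' @param val_f1,val_pcc equal-length numeric vectors, one value per
#'   epoch.
#' @return 1-based epoch index.
#' @export
#' @examples
#' select_checkpoint(c(0.9, 0.8, 0.7), c(0.1, 0.3, 0.2)) # epoch 2
select_checkpoint <- function(val_f1, val_pcc) {
  stopifnot(length(val_f1) == length(val_pcc), length(val_f1) >= 1L)
  r1 <- rank(-val_f1, ties.method = "average", na.last = "keep")
  r2 <- rank(-val_pcc, ties.method = "average", na.last = "keep")
  which.min((r1 + r2) / 2)
}

# ---- checkpoint files ---------------------------------------------------

#' Save a model checkpoint
#'
#' Writes a single-file archive of the parameters plus a JSON manifest
#' sidecar recording the architecture, gene panel, cell types and channel
#' statistics.
#'
#' @param model an `hx_model`.
#' @param stem output path without extension; writes `<stem>.rds` and
#'   `<stem>.json`.
#' @export
save_checkpoint <- function(model, stem) {
  saveRDS(model, paste0(stem, ".rds"))
  cfg <- model$config
  manifest <- list(mode = cfg$mode, genes = cfg$gene_names,
                   cell_types = cfg$cell_types,
                   backbone = cfg$backbone[c("levels", "base_width",
                                             "skip_width", "n_classes", "n_convs")],
                   embed_dim = cfg$embed_dim,
                   channel_mean = model$channel_mean,
                   channel_sd = model$channel_sd)
  jsonlite::write_json(manifest, paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' Load a model checkpoint saved by [save_checkpoint()]
#' @param stem path without extension.
#' @return The `hx_model`.
#' @export
load_checkpoint <- function(stem) readRDS(paste0(stem, ".rds"))
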