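# UNet3+-style encoder-decoder backbone performing joint per-pixel nuclei
# segmentation and cell-type classification. Five feature scales by
# default, full-scale skip connections aggregating every encoder/decoder
# scale into each decoder node, no deep supervision. Skip transforms are
# applied at the source resolution and then resized (block mean going
# down, nearest neighbour going up), which keeps the full-scale
# aggregation while avoiding convolutions on upsampled volumes.

#' Configure the segmentation backbone
#'
#' With the default widths each decoder node concatenates `levels`
#' aggregated sources of `skip_width` channels and fuses them to
#' `levels * skip_width` channels, so the full-resolution feature volume
#' has 320 channels and, together with the 64-channel first convolution,
#' yields the 384-dimensional per-nucleus pooled vector.
#'
#' @param levels number of feature scales (default 5).
#' @param base_width channels of the first convolution (default 64);
#'   encoder level `l` uses `base_width * 2^(l-1)` channels.
#' @param skip_width channels contributed per scale to each full-scale
#'   skip aggregation (default 64).
#' @param n_classes output classes: number of cell types + 1 background.
#' @param n_convs convolutions per encoder block (default 2).
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(levels = 5L, base_width = 64L, skip_width = 64L,
                            n_classes = 2L, n_convs = 2L) {
  stopifnot(levels >= 2L, base_width >= 1L, skip_width >= 1L,
            n_classes >= 2L, n_convs >= 1L)
  structure(list(levels = as.integer(levels),
                 base_width = as.integer(base_width),
                 skip_width = as.integer(skip_width),
                 n_classes = as.integer(n_classes),
                 n_convs = as.integer(n_convs),
                 enc_channels = as.integer(base_width * 2^(seq_len(levels) - 1L)),
                 last_channels = as.integer(levels * skip_width)),
            class = "backbone_config")
}

# He (fan-in) initialization for a conv/FC weight matrix of given shape
he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

#' Initialize backbone parameters
#'
#' He initialization (fan-in) for all weights; zero biases. Deterministic
#' given the current RNG state.
#'
#' @param cfg a [backbone_config()].
#' @return Named list of parameter arrays (conv weights are
#'   `(kh*kw*C_in) x C_out` matrices).
#' @export
backbone_init <- function(cfg) {
  p <- list()
  ch <- cfg$enc_channels
  L <- cfg$levels
  c_in <- 3L
  for (l in seq_len(L)) {
    for (j in seq_len(cfg$n_convs)) {
      nm <- sprintf("enc%d.conv%d", l, j)
      p[[paste0(nm, ".w")]] <- he_init(9L * c_in, ch[l])
      p[[paste0(nm, ".b")]] <- numeric(ch[l])
      c_in <- ch[l]
    }
  }
  for (d in seq.int(L - 1L, 1L)) {
    for (s in seq_len(L)) {
      c_src <- if (s <= d || s == L) ch[s] else cfg$last_channels
      nm <- sprintf("dec%d.src%d", d, s)
      p[[paste0(nm, ".w")]] <- he_init(9L * c_src, cfg$skip_width)
      p[[paste0(nm, ".b")]] <- numeric(cfg$skip_width)
    }
    nm <- sprintf("dec%d.fuse", d)
    p[[paste0(nm, ".w")]] <- he_init(9L * cfg$last_channels, cfg$last_channels)
    p[[paste0(nm, ".b")]] <- numeric(cfg$last_channels)
  }
  p[["cls.w"]] <- he_init(cfg$last_channels, cfg$n_classes)
  p[["cls.b"]] <- numeric(cfg$n_classes)
  p
}

check_divisible <- function(dims, levels) {
  div <- 2^(levels - 1L)
  if (any(dims[1:2] %% div != 0)) {
    stop(sprintf(paste0("backbone: spatial dims (%d x %d) must be divisible by ",
                        "2^(levels-1) = %d; crop or pad the patch accordingly"),
                 dims[1], dims[2], div))
  }
}

# autograd forward: x_node is an ag_node holding the standardized H x W x 3
# patch; pn is a named list of ag parameter leaves. Returns nodes.
bb_forward_ag <- function(x_node, cfg, pn) {
  check_divisible(dim(x_node$value), cfg$levels)
  L <- cfg$levels
  enc <- vector("list", L)
  first <- NULL
  h <- x_node
  for (l in seq_len(L)) {
    if (l > 1L) h <- ag_maxpool2(h)
    for (j in seq_len(cfg$n_convs)) {
      nm <- sprintf("enc%d.conv%d", l, j)
      h <- ag_relu(ag_conv2d(h, pn[[paste0(nm, ".w")]], pn[[paste0(nm, ".b")]]))
      if (l == 1L && j == 1L) first <- h
    }
    enc[[l]] <- h
  }
  dec <- vector("list", L)
  dec[[L]] <- enc[[L]]
  for (d in seq.int(L - 1L, 1L)) {
    parts <- vector("list", L)
    for (s in seq_len(L)) {
      src <- if (s <= d) enc[[s]] else dec[[s]]
      nm <- sprintf("dec%d.src%d", d, s)
      t <- ag_relu(ag_conv2d(src, pn[[paste0(nm, ".w")]], pn[[paste0(nm, ".b")]]))
      if (s < d) t <- ag_blockmean(t, 2L^(d - s))
      if (s > d) t <- ag_upnearest(t, 2L^(s - d))
      parts[[s]] <- t
    }
    nm <- sprintf("dec%d.fuse", d)
    dec[[d]] <- ag_relu(ag_conv2d(ag_concat_c(parts),
                                  pn[[paste0(nm, ".w")]], pn[[paste0(nm, ".b")]]))
  }
  logits <- ag_conv2d(dec[[1L]], pn[["cls.w"]], pn[["cls.b"]], kh = 1L, kw = 1L)
  list(logits = logits, first = first, last = dec[[1L]])
}

#' Run the backbone on a standardized patch
#'
#' @param patch numeric `h x w x 3` standardized array (see
#'   [standardize_patch()]); spatial dims must be divisible by
#'   `2^(levels-1)`.
#' @param cfg a [backbone_config()].
#' @param params parameters from [backbone_init()].
#' @return list with `class_probs` (`h x w x n_classes`, per-pixel
#'   simplex), `first_features` (`h x w x base_width`) and `last_features`
#'   (`h x w x levels*skip_width`).
#' @export
forward_backbone <- function(patch, cfg, params) {
  pn <- lapply(params, ag_leaf)
  out <- bb_forward_ag(ag_leaf(patch), cfg, pn)
  list(class_probs = cpp_softmax_spatial(out$logits$value),
       first_features = out$first$value,
       last_features = out$last$value)
}

#' Per-pixel segmentation/classification cross-entropy
#'
#' Mean over all pixels of the negative log predicted probability of the
#' true class (cell types and background), with probabilities clamped at
#' `eps` inside the log.
#'
#' @param probs `h x w x M` per-pixel class probability array.
#' @param target integer `h x w` matrix of 0-based true classes
#'   (0 = background).
#' @param eps clamping constant (default 1e-8).
#' @return Scalar loss.
#' @export
#' @examples
#' probs <- array(1 / 3, dim = c(2, 2, 3))
#' morphology_loss(probs, matrix(0L, 2, 2)) # log(3)
morphology_loss <- function(probs, target, eps = 1e-8) {
  d <- dim(probs)
  stopifnot(length(d) == 3L, all(dim(target) == d[1:2]))
  if (any(target < 0L | target >= d[3])) stop("morphology_loss: target class out of range")
  idx <- cbind(as.vector(row(target)), as.vector(col(target)), as.vector(target) + 1L)
  -mean(log(pmax(probs[idx], eps)))
}

#' Rasterize cell types onto an instance map
#'
#' Builds the backbone's per-pixel training target: background pixels are
#' class 0 and each nucleus pixel the 1-based index of its cell type.
#' Nuclei without a type (or not in `valid_ids`) are excluded with -1.
#'
#' @param map an [instance_map()].
#' @param cells a [cell_table()] with `type_true`.
#' @param cell_types ordered type labels defining the class indices.
#' @return Integer matrix of per-pixel classes (-1 = ignore).
#' @export
rasterize_types <- function(map, cells, cell_types) {
  target <- matrix(0L, nrow(map$labels), ncol(map$labels))
  lab <- map$labels
  for (i in seq_len(nrow(cells))) {
    id <- cells$id[i]
    cls <- match(cells$type_true[i], cell_types)
    v <- if (id %in% map$valid_ids && !is.na(cls)) cls else -1L
    target[lab == id] <- v
  }
  target[lab > 0L & !(lab %in% cells$id)] <- -1L
  target
}
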