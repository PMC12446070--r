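# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

# small synthetic dataset: 6 patches of 64 px, 3 types, 12 genes
tiny_dataset <- function() {
  if (is.null(.fx$ds)) {
    cfg <- sim_config(n_patches = 6L, patch_size = 64L, n_types = 3L,
                      n_genes = 12L, markers_per_type = 3L,
                      nuclei_per_patch = c(5L, 9L), seed = 42L)
    .fx$ds <- generate_dataset(cfg)
  }
  .fx$ds
}

# tiny trained-ready model matching tiny_dataset()
tiny_model <- function() {
  if (is.null(.fx$model)) {
    ds <- tiny_dataset()
    bb <- backbone_config(levels = 4L, base_width = 4L, skip_width = 4L,
                          n_convs = 1L)
    m <- hx_model_init(ds$ref$gene_names, paste0("type", 1:3),
                       reference = ds$ref, reference_scale = "raw_counts",
                       backbone = bb, embed_dim = 32L, head_hidden = 32L,
                       n_heads = 2L, d_head = 8L, target_types = "type1",
                       seed = 3L)
    cs <- channel_stats(ds$patches)
    m$channel_mean <- cs$mean
    m$channel_sd <- cs$sd
    .fx$model <- m
  }
  .fx$model
}

tiny_items <- function() {
  if (is.null(.fx$items)) {
    ds <- tiny_dataset()
    expr_log <- log_normalize(ds$expr)
    .fx$items <- prepare_items(ds$patches, ds$maps, ds$cells, expr_log,
                               paste0("type", 1:3))
  }
  .fx$items
}

# a realistic two-stain H&E-like patch built from known stain vectors
two_stain_patch <- function(seed = 3L, n_side = 64L, I0 = 240) {
  set.seed(seed)
  v1 <- c(0.65, 0.70, 0.29); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(0.07, 0.99, 0.11); v2 <- v2 / sqrt(sum(v2^2))
  n <- n_side * n_side
  conc <- cbind(stats::runif(n, 0.05, 1.2), stats::runif(n, 0.05, 0.8))
  od <- conc %*% rbind(v1, v2)
  pix <- round(pmin(pmax(I0 * 10^(-od) - 1, 0), 255))
  list(patch = he_patch(array(pix, c(n_side, n_side, 3)), mpp = 0.5),
       stains = cbind(v1, v2))
}

# random instance map with a few blob-like labels (possibly overlapping
# rectangles; later labels overwrite earlier ones)
random_label_map <- function(n_side = 24L, n_labels = 4L) {
  lab <- matrix(0L, n_side, n_side)
  for (id in seq_len(n_labels)) {
    h <- sample(2:6, 1L); w <- sample(2:6, 1L)
    r <- sample(seq_len(n_side - h), 1L); c <- sample(seq_len(n_side - w), 1L)
    lab[r:(r + h - 1L), c:(c + w - 1L)] <- id
  }
  lab
}
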