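# Evaluation: per-gene Pearson correlation, spatial SSIM on rasterized
# expression, cell-type classification metrics, stratified correlation
# summaries, and the spot-level metric rollup.

#' Per-gene Pearson correlation
#'
#' Correlation between predicted and ground-truth values of each gene
#' across cells. Genes that are constant in either matrix have no defined
#' correlation and are reported as `NA` (callers exclude them from
#' averages rather than imputing a value).
#'
#' @param pred,truth [expression_matrix()] objects (or plain matrices)
#'   with identical dimensions and gene order; at least 2 cells.
#' @return tibble with columns `gene` and `pcc`.
#' @export
per_gene_pcc <- function(pred, truth) {
  p <- if (inherits(pred, "expression_matrix")) pred$values else as.matrix(pred)
  t <- if (inherits(truth, "expression_matrix")) truth$values else as.matrix(truth)
  stopifnot(all(dim(p) == dim(t)))
  if (nrow(p) < 2L) stop("per_gene_pcc: need at least 2 cells")
  genes <- colnames(p) %||% paste0("gene", seq_len(ncol(p)))
  pcc <- vapply(seq_len(ncol(p)), function(j) {
    if (stats::sd(p[, j]) == 0 || stats::sd(t[, j]) == 0) return(NA_real_)
    stats::cor(p[, j], t[, j])
  }, numeric(1))
  tibble::tibble(gene = genes, pcc = pcc)
}

# separable Gaussian filter, valid region only
gaussian_filter_valid <- function(x, win, sigma) {
  half <- (win - 1L) / 2L
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g <- g / sum(g)
  n <- nrow(x) - win + 1L
  m <- ncol(x) - win + 1L
  rows <- matrix(0, n, ncol(x))
  for (i in seq_len(win)) rows <- rows + g[i] * x[i:(i + n - 1L), , drop = FALSE]
  out <- matrix(0, n, m)
  for (j in seq_len(win)) out <- out + g[j] * rows[, j:(j + m - 1L), drop = FALSE]
  out
}

#' Structural similarity between two single-channel images
#'
#' Gaussian-weighted local statistics (11 x 11 window, sigma 1.5),
#' stability constants `(K1*L)^2` and `(K2*L)^2` with `K1 = 0.01`,
#' `K2 = 0.03`, averaged over the valid filter region.
#'
#' @param x,y numeric matrices of identical size, at least the window
#'   size in each dimension.
#' @param dynamic_range the data range `L`; must be positive.
#' @param K1,K2,win,sigma standard SSIM constants.
#' @return Scalar mean SSIM.
#' @export
ssim <- function(x, y, dynamic_range, K1 = 0.01, K2 = 0.03,
                 win = 11L, sigma = 1.5) {
  stopifnot(all(dim(x) == dim(y)), dynamic_range > 0)
  if (nrow(x) < win || ncol(x) < win) {
    stop("ssim: image smaller than the filter window")
  }
  c1 <- (K1 * dynamic_range)^2
  c2 <- (K2 * dynamic_range)^2
  f <- function(z) gaussian_filter_valid(z, win, sigma)
  mx <- f(x); my <- f(y)
  vx <- f(x^2) - mx^2
  vy <- f(y^2) - my^2
  cxy <- f(x * y) - mx * my
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

#' Rasterize per-cell expression onto a regular grid
#'
#' Bins cell centroids into a `grid x grid` lattice over the given extent
#' and sums expression per bin, producing one image per gene.
#'
#' @param expr [expression_matrix()] or matrix, cells x genes.
#' @param rows,cols cell centroid coordinates (pixels).
#' @param extent `c(H, W)` of the underlying image.
#' @param grid lattice size per side (default 32).
#' @return `grid x grid x n_genes` array.
#' @export
rasterize_expression <- function(expr, rows, cols, extent, grid = 32L) {
  v <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  stopifnot(length(rows) == nrow(v), length(cols) == nrow(v))
  bi <- pmin(pmax(ceiling(rows / extent[1] * grid), 1L), grid)
  bj <- pmin(pmax(ceiling(cols / extent[2] * grid), 1L), grid)
  bin <- (bj - 1L) * grid + bi
  out <- array(0, dim = c(grid, grid, ncol(v)))
  for (g in seq_len(ncol(v))) {
    acc <- rowsum(v[, g], group = bin)
    plane <- numeric(grid * grid)
    plane[as.integer(rownames(acc))] <- acc
    out[, , g] <- matrix(plane, grid, grid)
  }
  dimnames(out) <- list(NULL, NULL, colnames(v))
  out
}

#' Per-gene spatial SSIM of predicted versus true expression
#'
#' Rasterizes both matrices with [rasterize_expression()] and computes
#' SSIM per gene. The dynamic range is each gene's range in the truth
#' raster; genes with zero truth range are reported as `NA`.
#'
#' @inheritParams rasterize_expression
#' @param pred,truth cells x genes matrices (same cells, same order).
#' @return tibble with columns `gene` and `ssim`.
#' @export
ssim_per_gene <- function(pred, truth, rows, cols, extent, grid = 32L) {
  rp <- rasterize_expression(pred, rows, cols, extent, grid)
  rt <- rasterize_expression(truth, rows, cols, extent, grid)
  genes <- dimnames(rt)[[3]] %||% paste0("gene", seq_len(dim(rt)[3]))
  val <- vapply(seq_len(dim(rt)[3]), function(g) {
    L <- max(rt[, , g]) - min(rt[, , g])
    if (L <= 0) return(NA_real_)
    ssim(rp[, , g], rt[, , g], dynamic_range = L)
  }, numeric(1))
  tibble::tibble(gene = genes, ssim = val)
}

#' Cell-type classification metrics
#'
#' Accuracy, per-class F1, macro-averaged F1 and the predicted and true
#' composition vectors. Classes are the union of labels seen in either
#' vector (plus `levels` if given); classes absent from both predictions
#' and truth contribute an F1 of 0.
#'
#' @param pred,truth character label vectors of equal length.
#' @param levels optional label universe fixing the class order.
#' @return list with `accuracy`, `f1` (named vector), `macro_f1`,
#'   `composition_pred`, `composition_true`.
#' @export
celltype_metrics <- function(pred, truth, levels = NULL) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1L)
  lv <- levels %||% sort(unique(c(pred, truth)))
  if (!all(c(pred, truth) %in% lv)) {
    stop("celltype_metrics: labels outside the given levels")
  }
  pi <- factor(pred, levels = lv)
  ti <- factor(truth, levels = lv)
  cm <- table(ti, pi)
  tp <- diag(cm)
  f1 <- vapply(seq_along(lv), function(k) {
    denom <- sum(cm[k, ]) + sum(cm[, k])
    if (denom == 0) 0 else 2 * tp[k] / denom
  }, numeric(1))
  names(f1) <- lv
  list(accuracy = mean(pred == truth),
       f1 = f1,
       macro_f1 = mean(f1),
       composition_pred = as.numeric(table(pi)) / length(pred),
       composition_true = as.numeric(table(ti)) / length(truth))
}

#' Rank genes by variance of their log-normalized values
#'
#' The fallback ranking for highly variable genes when no external
#' variability annotation exists.
#'
#' @param expr log-normalized [expression_matrix()] (raw counts are
#'   log1p-transformed first).
#' @param k number of genes to return; must not exceed the panel size.
#' @return Character vector of the `k` most variable genes, most variable
#'   first.
#' @export
top_variable_genes <- function(expr, k) {
  v <- expr$values
  if (expr$scale == "raw_counts") v <- log1p(v)
  if (k > ncol(v)) stop("top_variable_genes: k exceeds the gene panel")
  vars <- apply(v, 2L, stats::var)
  colnames(v)[order(-vars)][seq_len(k)]
}

#' Stratified correlation summary
#'
#' Median and quartiles of a per-gene metric within named gene sets (for
#' example spatially variable versus highly variable genes); `NA` metric
#' values are excluded.
#'
#' @param per_gene tibble with columns `gene` and a metric column.
#' @param gene_sets named list of gene-name character vectors.
#' @param metric name of the metric column (default `"pcc"`).
#' @return tibble with columns `set`, `n`, `median`, `q25`, `q75`.
#' @export
stratified_correlation <- function(per_gene, gene_sets, metric = "pcc") {
  stopifnot(metric %in% names(per_gene))
  rows <- lapply(names(gene_sets), function(nm) {
    miss <- setdiff(gene_sets[[nm]], per_gene$gene)
    if (length(miss) > 0L) {
      stop("stratified_correlation: genes absent from the metric table: ",
           paste(utils::head(miss, 3L), collapse = ", "))
    }
    v <- per_gene[[metric]][per_gene$gene %in% gene_sets[[nm]]]
    v <- v[!is.na(v)]
    q <- if (length(v) > 0L) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
         else rep(NA_real_, 3L)
    tibble::tibble(set = nm, n = length(v), median = q[2], q25 = q[1], q75 = q[3])
  })
  dplyr::bind_rows(rows)
}

#' Roll spot-level metrics up to one value per gene
#'
#' Hierarchical averaging that prevents individuals with many images from
#' dominating: per-gene metrics are first averaged over each individual's
#' images, then over individuals.
#'
#' @param per_image tibble with columns `image`, `gene` and a metric
#'   column.
#' @param individuals named character vector mapping image identifiers to
#'   individual identifiers; every image must be mapped.
#' @param metric name of the metric column (default `"pcc"`).
#' @return tibble with columns `gene` and `value`.
#' @export
spot_metric_rollup <- function(per_image, individuals, metric = "pcc") {
  stopifnot(all(c("image", "gene", metric) %in% names(per_image)))
  unmapped <- setdiff(unique(per_image$image), names(individuals))
  if (length(unmapped) > 0L) {
    stop("spot_metric_rollup: images without an individual: ",
         paste(unmapped, collapse = ", "))
  }
  df <- per_image
  df$individual <- individuals[df$image]
  df$value <- df[[metric]]
  df |>
    dplyr::group_by(.data$individual, .data$gene) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

# ---- tidiers and plots --------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-epoch training metrics
#' @param x an `hx_fit`.
#' @param ... unused.
#' @return The per-epoch metrics tibble with a `selected` flag.
#' @export
tidy.hx_fit <- function(x, ...) {
  dplyr::mutate(x$metrics, selected = .data$epoch == x$selected_epoch)
}

#' One-row fit summary
#' @param x an `hx_fit`.
#' @param ... unused.
#' @export
glance.hx_fit <- function(x, ...) {
  m <- x$metrics[x$selected_epoch, ]
  tibble::tibble(epochs = nrow(x$metrics), selected_epoch = x$selected_epoch,
                 train_loss = m$train_loss, val_f1 = m$val_f1, val_pcc = m$val_pcc)
}

#' Plot training curves
#'
#' Loss and validation metrics by epoch, with the selected checkpoint
#' marked.
#'
#' @param object an `hx_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hx_fit <- function(object, ...) {
  df <- tidy.hx_fit(object)
  long <- tidyr::pivot_longer(
    df[, c("epoch", "train_loss", "val_f1", "val_pcc")],
    cols = -"epoch", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$selected_epoch, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot predicted against true per-gene correlation-ready expression
#'
#' Scatter of predicted versus true values for one gene across cells.
#'
#' @param pred,truth [expression_matrix()] objects.
#' @param gene gene name.
#' @return A ggplot object.
#' @export
plot_gene_scatter <- function(pred, truth, gene) {
  stopifnot(gene %in% pred$gene_names, gene %in% truth$gene_names)
  df <- tibble::tibble(truth = truth$values[, gene], pred = pred$values[, gene])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$pred)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "true expression", y = "predicted expression", title = gene)
}
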