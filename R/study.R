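# The self-contained synthetic recovery study: generate a dataset, train
# the reduced-width model, and evaluate cell typing and expression on
# held-out patches. This is the package's reference end-to-end
# computation, shared by the test suite and the command-line entry point.

#' Run the end-to-end synthetic recovery study
#'
#' Generates a synthetic dataset, splits its patches into train /
#' validation / test partitions, trains the multitask model at reduced
#' width, and evaluates held-out cell-type accuracy and per-gene Pearson
#' correlation of the predicted expression. Every random draw derives
#' from `cfg$seed` and the model/training seeds, so results are
#' bit-reproducible.
#'
#' @param cfg a [sim_config()]; defaults to the study condition of
#'   200 patches of 128 x 128 pixels, 4 cell types and 24 genes.
#' @param backbone reduced-width [backbone_config()].
#' @param train a [train_config()]; defaults to 8 epochs with a
#'   training seed derived from `cfg$seed`.
#' @param embed_dim,head_hidden,n_heads,d_head reduced head geometry.
#' @param val_fraction,test_fraction patch fractions held out for
#'   checkpoint selection and final evaluation.
#' @param verbose print epoch progress.
#' @return list with `fit` (the [train_model()] result), `accuracy`,
#'   `macro_f1`, `per_gene` (tibble of per-gene PCC), `hvg` (the 5
#'   most variable genes in the held-out truth), `mean_pcc_hvg`,
#'   `n_test_cells`, and the index vectors of the three partitions.
#' @export
run_synthetic_study <- function(cfg = sim_config(n_patches = 200L),
                                backbone = backbone_config(levels = 5L,
                                                           base_width = 8L,
                                                           skip_width = 4L,
                                                           n_convs = 1L),
                                train = train_config(epochs = 8L,
                                                     seed = cfg$seed + 2L),
                                embed_dim = 64L, head_hidden = 64L,
                                n_heads = 2L, d_head = 8L,
                                val_fraction = 0.1, test_fraction = 0.2,
                                verbose = TRUE) {
  ds <- generate_dataset(cfg)
  expr_log <- log_normalize(ds$expr)
  types <- ds$ref$profile_names
  model <- hx_model_init(ds$ref$gene_names, types, reference = ds$ref,
                         reference_scale = "raw_counts", backbone = backbone,
                         embed_dim = embed_dim, head_hidden = head_hidden,
                         n_heads = n_heads, d_head = d_head,
                         seed = cfg$seed + 1L)
  items <- prepare_items(ds$patches, ds$maps, ds$cells, expr_log, types)
  n <- length(items)
  n_test <- max(1L, round(test_fraction * n))
  n_val <- max(1L, round(val_fraction * n))
  idx_test <- seq_len(n_test)
  idx_val <- n_test + seq_len(n_val)
  idx_train <- setdiff(seq_len(n), c(idx_test, idx_val))
  fit <- train_model(items[idx_train], items[idx_val], model, train,
                     verbose = verbose)
  preds <- integer(); truth <- integer()
  yp <- list(); yt <- list()
  for (it in items[idx_test]) {
    if (length(it$type_idx) == 0L) next
    fw <- hx_forward_patch(fit$model, it$patch, it$map)
    preds <- c(preds, apply(fw$ct_logits, 1L, which.max))
    truth <- c(truth, it$type_idx)
    yp[[length(yp) + 1L]] <- fw$y_prime
    yt[[length(yt) + 1L]] <- it$y_log
  }
  cm <- celltype_metrics(types[preds], types[truth], levels = types)
  yp <- do.call(rbind, yp)
  yt <- do.call(rbind, yt)
  per_gene <- per_gene_pcc(yp, yt)
  per_gene$gene <- ds$ref$gene_names
  hvg <- top_variable_genes(expression_matrix(yt, ds$ref$gene_names,
                                              scale = "log_normalized"), 5L)
  list(fit = fit, accuracy = cm$accuracy, macro_f1 = cm$macro_f1,
       f1 = cm$f1, per_gene = per_gene, hvg = hvg,
       mean_pcc_hvg = mean(per_gene$pcc[per_gene$gene %in% hvg], na.rm = TRUE),
       n_test_cells = length(truth),
       idx_train = idx_train, idx_val = idx_val, idx_test = idx_test)
}
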