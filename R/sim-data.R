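# Synthetic H&E-like data with fully known ground truth: elliptical nuclei
# of several cell types rendered on a pink-white background, spatially
# clustered type assignment, and per-cell expression drawn from
# type-specific reference profiles. Every downstream stage is testable
# against the generating truth without any download.

.sim_palette_base <- matrix(c(
  60, 45, 130,   # blue-purple
  140, 40, 70,   # crimson
  40, 110, 100,  # teal
  150, 100, 40,  # ochre
  90, 90, 90,    # gray
  30, 60, 140,   # blue
  120, 50, 140,  # violet
  70, 130, 50    # green
), ncol = 3, byrow = TRUE)

#' Configure the synthetic histology generator
#'
#' Defaults describe a desk-scale study: a handful of visually distinct cell
#' types whose nuclei are non-overlapping ellipses with type-specific color,
#' spatially clustered type assignment (one spatial blob per type, blended
#' with a uniform prior by `neighborhood_mixing`), and Poisson expression
#' around type-specific reference profiles with per-gene log-normal noise.
#'
#' @param n_types number of cell types.
#' @param n_genes gene panel size; must be at least
#'   `n_types * markers_per_type`.
#' @param markers_per_type marker genes per type (disjoint blocks).
#' @param patch_size patch side length in pixels.
#' @param n_patches number of patches in a dataset.
#' @param nuclei_per_patch length-2 (min, max) nuclei per patch.
#' @param nucleus_radius length-2 (min, max) ellipse semi-axis in pixels.
#' @param neighborhood_mixing scalar in `[0, 1]`: 1 = types drawn i.i.d.
#'   from the uniform prior, 0 = fully determined by the spatial blobs.
#' @param noise_sd standard deviation of the per-gene log-scale expression
#'   noise.
#' @param seed integer seed; the generator is fully reproducible given it.
#' @param palette `"easy"` (well-separated nucleus colors) or `"hard"`
#'   (types 1 and 2 nearly identical, exercising the composition-guided
#'   recovery mechanism).
#' @param mpp microns per pixel of the rendered patches.
#' @param size_factor multiplier on profile means when drawing counts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_types = 4L, n_genes = 24L, markers_per_type = 3L,
                       patch_size = 128L, n_patches = 20L,
                       nuclei_per_patch = c(8L, 16L),
                       nucleus_radius = c(5, 9),
                       neighborhood_mixing = 0.3, noise_sd = 0.3,
                       seed = 1L, palette = c("easy", "hard"),
                       mpp = 0.5, size_factor = 1) {
  palette <- match.arg(palette)
  stopifnot(n_types >= 1L, n_genes >= 1L, markers_per_type >= 1L,
            patch_size >= 16L, n_patches >= 1L)
  if (n_genes < n_types * markers_per_type) {
    stop("sim_config: n_genes must be >= n_types * markers_per_type")
  }
  stopifnot(length(nuclei_per_patch) == 2L, nuclei_per_patch[1] >= 1L,
            length(nucleus_radius) == 2L, nucleus_radius[1] >= 1,
            neighborhood_mixing >= 0, neighborhood_mixing <= 1,
            noise_sd >= 0, n_types <= nrow(.sim_palette_base))
  structure(list(n_types = as.integer(n_types), n_genes = as.integer(n_genes),
                 markers_per_type = as.integer(markers_per_type),
                 patch_size = as.integer(patch_size),
                 n_patches = as.integer(n_patches),
                 nuclei_per_patch = as.integer(nuclei_per_patch),
                 nucleus_radius = nucleus_radius,
                 neighborhood_mixing = neighborhood_mixing,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 palette = palette, mpp = mpp, size_factor = size_factor),
            class = "sim_config")
}

# run expr under a derived, restored RNG substream so that independent parts
# of the generator (layout / rendering / expression) do not perturb each
# other when unrelated config fields change
with_substream <- function(seed, offset, expr) {
  s <- (as.double(seed) * 48271 + offset) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(s))
  expr
}

sim_palette <- function(cfg) {
  cols <- .sim_palette_base[seq_len(cfg$n_types), , drop = FALSE]
  if (cfg$palette == "hard" && cfg$n_types >= 2L) {
    cols[2L, ] <- pmin(255, pmax(0, cols[1L, ] + c(6, 4, -5)))
  }
  cols
}

#' Generate type-specific reference expression profiles
#'
#' Each type receives a disjoint block of `markers_per_type` marker genes
#' whose mean expression is well above (at least 5x) the off-marker
#' baseline. Values are mean transcript counts. Deterministic given the
#' config seed.
#'
#' @param cfg a [sim_config()].
#' @return A [reference_profiles()] with `n_types` rows.
#' @export
generate_reference_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_substream(cfg$seed, 11L, {
    R <- matrix(stats::runif(cfg$n_types * cfg$n_genes, 0.25, 1.5),
                cfg$n_types, cfg$n_genes)
    for (k in seq_len(cfg$n_types)) {
      j <- ((k - 1L) * cfg$markers_per_type + 1L):(k * cfg$markers_per_type)
      R[k, j] <- stats::runif(cfg$markers_per_type, 15, 30)
    }
    reference_profiles(R,
                       profile_names = paste0("type", seq_len(cfg$n_types)),
                       gene_names = sprintf("gene%02d", seq_len(cfg$n_genes)))
  })
}

# pixel set of an ellipse at (cy, cx) with semi-axes (a, b) and angle theta,
# clipped to the patch; returns 2-column (row, col) 1-based matrix
ellipse_pixels <- function(cy, cx, a, b, theta, size) {
  r <- ceiling(max(a, b))
  ys <- max(1L, floor(cy - r)):min(size, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(size, ceiling(cx + r))
  g <- expand.grid(row = ys, col = xs)
  dy <- g$row - cy
  dx <- g$col - cx
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  as.matrix(g[u^2 + v^2 <= 1, , drop = FALSE])
}

#' Render one synthetic H&E patch
#'
#' Places non-overlapping elliptical nuclei by rejection sampling, assigns
#' each a cell type from a spatial blob process (one attractor per type,
#' blended with a uniform prior by `neighborhood_mixing`), and paints each
#' type with its palette color plus texture noise on a pink-white
#' background. Placement failures after bounded retries yield fewer nuclei,
#' never an error.
#'
#' @param cfg a [sim_config()].
#' @param patch_index 1-based index selecting the per-patch random
#'   substream.
#' @return list with `patch` ([he_patch()]), `map` ([instance_map()]) and
#'   `cells` ([cell_table()]).
#' @export
render_patch <- function(cfg, patch_index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_substream(cfg$seed, 100L + patch_index, {
    size <- cfg$patch_size
    n_try <- sample(cfg$nuclei_per_patch[1]:cfg$nuclei_per_patch[2], 1L)
    centers_type <- cbind(stats::runif(cfg$n_types, 1, size),
                          stats::runif(cfg$n_types, 1, size))
    sigma <- size / 3
    occ <- matrix(FALSE, size, size)
    labels <- matrix(0L, size, size)
    rows <- list()
    lab <- 0L
    for (i in seq_len(n_try)) {
      placed <- FALSE
      for (attempt in 1:40) {
        a <- stats::runif(1, cfg$nucleus_radius[1], cfg$nucleus_radius[2])
        b <- stats::runif(1, cfg$nucleus_radius[1], cfg$nucleus_radius[2])
        th <- stats::runif(1, 0, pi)
        r <- max(a, b)
        cy <- stats::runif(1, 1 + r, size - r)
        cx <- stats::runif(1, 1 + r, size - r)
        pix <- ellipse_pixels(cy, cx, a, b, th, size)
        if (nrow(pix) >= 1L && !any(occ[pix])) {
          placed <- TRUE
          break
        }
      }
      if (!placed) next
      # spatial blob process for the type
      d2 <- (centers_type[, 1] - cy)^2 + (centers_type[, 2] - cx)^2
      w <- exp(-d2 / (2 * sigma^2))
      w <- w / sum(w)
      prior <- rep(1 / cfg$n_types, cfg$n_types)
      pt <- cfg$neighborhood_mixing * prior + (1 - cfg$neighborhood_mixing) * w
      type <- sample.int(cfg$n_types, 1L, prob = pt)
      lab <- lab + 1L
      occ[pix] <- TRUE
      labels[pix] <- lab
      rows[[lab]] <- tibble::tibble(
        id = lab,
        centroid_row = mean(pix[, 1]) - 1, centroid_col = mean(pix[, 2]) - 1,
        area_px = nrow(pix), type_true = paste0("type", type))
    }
    img <- array(0, dim = c(size, size, 3))
    bg <- c(248, 226, 233)
    for (c in 1:3) {
      img[, , c] <- bg[c] + matrix(stats::rnorm(size * size, 0, 4), size, size)
    }
    cols <- sim_palette(cfg)
    if (lab > 0L) {
      type_idx <- as.integer(sub("type", "", vapply(rows, function(r) r$type_true, "")))
      for (i in seq_len(lab)) {
        sel <- labels == i
        npx <- sum(sel)
        for (c in 1:3) {
          img[, , c][sel] <- cols[type_idx[i], c] + stats::rnorm(npx, 0, 8)
        }
      }
    }
    img <- round(pmin(pmax(img, 0), 255))
    cells <- if (lab > 0L) {
      cell_table(dplyr::bind_rows(rows), mpp = cfg$mpp)
    } else {
      cell_table(tibble::tibble(id = integer(), centroid_row = numeric(),
                                centroid_col = numeric(), area_px = numeric(),
                                area_um2 = numeric(), type_true = character()))
    }
    list(patch = he_patch(img, mpp = cfg$mpp),
         map = instance_map(labels),
         cells = cells)
  })
}

#' Generate a full synthetic dataset
#'
#' Renders `n_patches` patches and draws per-cell expression as
#' `Poisson(size_factor * R[type, ] * exp(eps))` with
#' `eps ~ Normal(0, noise_sd)` independently per gene and cell. Per-patch
#' neighborhood compositions are the empirical type frequencies. Layout,
#' rendering and expression use independent random substreams, so changing
#' `n_genes` leaves the geometry untouched; everything is byte-identical
#' under the same seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `patches` (list of [he_patch()]), `maps` (list of
#'   [instance_map()]), `cells` (one [cell_table()] with a `patch` column
#'   and globally unique `cell` ids), `expr` (raw-count
#'   [expression_matrix()] aligned to `cells`), `ref` (the generating
#'   [reference_profiles()]), `nc` (n_patches x n_types composition matrix)
#'   and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ref <- generate_reference_profiles(cfg)
  rendered <- lapply(seq_len(cfg$n_patches), function(i) render_patch(cfg, i))
  cells <- dplyr::bind_rows(lapply(seq_len(cfg$n_patches), function(i) {
    ci <- rendered[[i]]$cells
    if (nrow(ci) > 0L) ci$patch <- i
    ci
  }))
  cells$cell <- seq_len(nrow(cells))
  type_idx <- match(cells$type_true, ref$profile_names)
  expr_vals <- with_substream(cfg$seed, 900017L, {
    n <- nrow(cells)
    out <- matrix(0, n, cfg$n_genes)
    for (i in seq_len(n)) {
      eps <- stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
      lam <- cfg$size_factor * ref$R[type_idx[i], ] * exp(eps)
      out[i, ] <- stats::rpois(cfg$n_genes, lam)
    }
    out
  })
  expr <- expression_matrix(expr_vals, gene_names = ref$gene_names,
                            scale = "raw_counts")
  nc <- t(vapply(seq_len(cfg$n_patches), function(i) {
    idx <- type_idx[cells$patch == i]
    tabulate(idx, nbins = cfg$n_types) / max(1L, length(idx))
  }, numeric(cfg$n_types)))
  colnames(nc) <- ref$profile_names
  list(patches = lapply(rendered, `[[`, "patch"),
       maps = lapply(rendered, `[[`, "map"),
       cells = cells, expr = expr, ref = ref, nc = nc, config = cfg)
}

#' Write a synthetic dataset to disk in the standard formats
#'
#' PNG patches, 16-bit TIFF instance maps, cell table CSV, expression CSV
#' and MTX, reference CSV and per-patch composition CSV.
#'
#' @param ds result of [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ds$patches)) {
    write_he_patch(ds$patches[[i]], file.path(dir, sprintf("patch%03d.png", i)))
    write_instance_map(ds$maps[[i]], file.path(dir, sprintf("patch%03d_labels.tif", i)))
  }
  utils::write.csv(ds$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write_expression_csv(ds$expr, file.path(dir, "expression.csv"))
  write_expression_mtx(ds$expr, file.path(dir, "expression"), cell_ids = ds$cells$cell)
  write_reference_csv(ds$ref, file.path(dir, "reference_profiles.csv"))
  utils::write.csv(as.data.frame(ds$nc), file.path(dir, "neighborhood_composition.csv"),
                   row.names = FALSE)
  invisible(dir)
}
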