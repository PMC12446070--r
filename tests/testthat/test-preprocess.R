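test_that("filter_transcripts keeps the qv threshold inclusive and drops controls", {
  tr <- tibble::tibble(
    gene = c("ACTB", "NegControlProbe_1", "BLANK_7", "antisense_X",
             "DeprecatedCodeword_3", "CD3E", "EPCAM"),
    qv = c(25, 40, 40, 40, 40, 20.0, 19.999))
  out <- filter_transcripts(tr)
  expect_identical(out$gene, c("ACTB", "CD3E"))
  expect_true(20.0 %in% out$qv)
  expect_error(filter_transcripts(tr[, "gene", drop = FALSE]), "missing columns")
  expect_identical(nrow(filter_transcripts(tr[0, ])), 0L)
})

test_that("match_nuclei keeps the larger of two candidates and applies the inclusive threshold", {
  # H&E nucleus of 20 px overlapped 60% / 55%-ish by two SST objects
  he <- matrix(0L, 10, 10); he[1:4, 1:5] <- 1L            # 20 px
  sst <- matrix(0L, 10, 10)
  sst[1:4, 1:3] <- 2L                                      # 12 px = 60%
  sst[1:4, 4:5] <- 7L                                      # 8 px = 40%
  m <- match_nuclei(instance_map(he), instance_map(sst))
  expect_identical(m$sst_id, 2L)
  expect_equal(m$overlap_fraction, 0.6)
  # exactly 50% is kept (inclusive)
  he2 <- matrix(0L, 10, 10); he2[1:4, 1:5] <- 1L
  sst2 <- matrix(0L, 10, 10); sst2[1:2, 1:5] <- 3L         # 10 px = 50%
  expect_identical(nrow(match_nuclei(instance_map(he2), instance_map(sst2))), 1L)
  # just under 50% is dropped
  sst3 <- matrix(0L, 10, 10); sst3[1:2, 1:4] <- 3L; sst3[3, 1] <- 3L  # 9 px
  expect_identical(nrow(match_nuclei(instance_map(he2), instance_map(sst3))), 0L)
})

test_that("match_nuclei ties break toward the smaller spatial id", {
  he <- matrix(0L, 6, 6); he[1:4, 1:4] <- 1L
  sst <- matrix(0L, 6, 6); sst[1:2, 1:4] <- 9L; sst[3:4, 1:4] <- 4L
  m <- match_nuclei(instance_map(he), instance_map(sst))
  expect_identical(m$sst_id, 4L)
})

test_that("match_nuclei agrees with a pixel-counting brute force on random maps", {
  set.seed(99)
  for (rep in 1:25) {
    he <- random_label_map(); sst <- random_label_map(n_labels = 5L)
    got <- match_nuclei(instance_map(he), instance_map(sst), min_overlap = 0.5)
    ids <- sort(unique(he[he > 0L]))
    for (id in ids) {
      sel <- he == id
      counts <- table(sst[sel & sst > 0L])
      row <- got[got$he_id == id, ]
      if (length(counts) == 0L) {
        expect_identical(nrow(row), 0L)
        next
      }
      best_n <- max(counts)
      cand <- as.integer(names(counts)[counts == best_n])
      best <- min(cand)
      if (best_n / sum(sel) >= 0.5) {
        expect_identical(row$sst_id, best)
        expect_identical(row$overlap_px, as.integer(best_n))
      } else {
        expect_identical(nrow(row), 0L)
      }
    }
  }
})

test_that("filter_cells drops zero-count, unassigned and small nuclei (strict)", {
  cells <- cell_table(tibble::tibble(
    id = 1:4, centroid_row = 1:4, centroid_col = 1:4,
    area_px = c(100, 100, 100, 100),
    area_um2 = c(25, 9.99, 10.0, 25),
    type_true = c("T cell", "B cell", "B cell", "unassigned")))
  expr <- expression_matrix(matrix(c(0, 0, 5, 5, 5, 5, 5, 5), 4, 2,
                                   dimnames = list(NULL, c("g1", "g2"))),
                            scale = "raw_counts")
  expr$values[1, ] <- 0                       # zero total count
  out <- filter_cells(cells, expr)
  expect_identical(out$cells$id, 3L)          # 1: zero count, 2: <10, 4: unassigned
  expect_identical(nrow(out$expr$values), 1L)
  # area exactly 10 is kept
  expect_true(10.0 %in% out$cells$area_um2)
  expect_error(filter_cells(cells[1:3, ], expr), "misaligned")
  # nothing to drop leaves input unchanged
  ok <- filter_cells(cells[3, ], expression_matrix(
    matrix(c(5, 5), 1, 2, dimnames = list(NULL, c("g1", "g2"))),
    scale = "raw_counts"))
  expect_identical(ok$cells$id, 3L)
})

test_that("tile_patches reproduces the worked stride examples", {
  t1 <- tile_patches(c(512, 512), 256, 0)
  expect_identical(nrow(t1), 4L)
  expect_setequal(t1$row0, c(0L, 256L))
  t2 <- tile_patches(c(482, 482), 256, 30)
  expect_setequal(unique(t2$col0), c(0L, 226L))
  expect_error(tile_patches(c(100, 100), 128, 30), "exceeds")
})

test_that("tilings cover every pixel for random extents", {
  set.seed(4)
  for (rep in 1:30) {
    H <- sample(20:60, 1); W <- sample(20:60, 1)
    size <- sample(5:min(H, W), 1)
    overlap <- sample(0:(size - 1), 1)
    tl <- tile_patches(c(H, W), size, overlap)
    cov <- matrix(FALSE, H, W)
    for (i in seq_len(nrow(tl))) {
      cov[tl$row0[i] + seq_len(size), tl$col0[i] + seq_len(size)] <- TRUE
    }
    expect_true(all(cov))
    expect_true(all(tl$row0 + size <= H), label = "tiles end inside the image")
    expect_true(all(tl$col0 + size <= W))
  }
})

test_that("cv splits form five disjoint covering test bands with a tenth-height validation strip", {
  H <- 1000L
  sp <- make_cv_splits(c(H, 400L), k = 5L)
  test_rows <- sp[sp$role == "test", ]
  expect_identical(nrow(test_rows), 5L)
  expect_equal(sum(test_rows$row_end - test_rows$row_start), H)
  for (f in 1:5) {
    sf <- sp[sp$fold == f, ]
    val <- sf[sf$role == "val", ]
    expect_equal(val$row_end - val$row_start, floor(H / 10))
    # roles partition all rows
    covered <- integer(0)
    for (i in seq_len(nrow(sf))) {
      covered <- c(covered, seq.int(sf$row_start[i], sf$row_end[i] - 1L))
    }
    expect_setequal(covered, 0:(H - 1L))
    expect_identical(anyDuplicated(covered), 0L)
  }
})

test_that("spot patches follow the 224 -> 112 -> 256 geometry", {
  set.seed(8)
  img <- array(runif(300 * 300 * 3, 0, 255), c(300, 300, 3))
  spots <- tibble::tibble(spot_id = c("s1", "s2"),
                          center_row = c(150, 2), center_col = c(150, 2))
  ps <- make_spot_patches(img, spots, mpp = 1)
  expect_identical(dim(ps[[1]]$pixels), c(256L, 256L, 3L))
  expect_equal(ps[[1]]$mpp, 112 / 256)
  # border spot handled by reflection, still full size and in range
  expect_identical(dim(ps[[2]]$pixels), c(256L, 256L, 3L))
  expect_true(all(ps[[2]]$pixels >= 0 & ps[[2]]$pixels <= 255))
  expect_error(make_spot_patches(img, tibble::tibble(
    spot_id = "x", center_row = -5, center_col = 10)), "inside")
})

test_that("spot gene selection takes the per-section union minus rare genes", {
  g <- paste0("g", 1:6)
  s1 <- matrix(0, 40, 6, dimnames = list(NULL, g))
  s2 <- matrix(0, 40, 6, dimnames = list(NULL, g))
  s1[, 1] <- rpois(40, 20); s1[, 2] <- rpois(40, 20)   # variable in s1
  s2[, 3] <- rpois(40, 20); s2[, 4] <- rpois(40, 20)   # variable in s2
  s1[, 5] <- 1; s2[, 5] <- 1                            # expressed, constant
  sel <- select_spot_genes(list(s1, s2), top_k = 2L, min_spots = 30L)
  expect_setequal(sel, c("g1", "g2", "g3", "g4"))
  # raising min_spots above prevalence drops genes expressed in one section only
  sel2 <- select_spot_genes(list(s1, s2), top_k = 2L, min_spots = 50L)
  expect_identical(sel2, character(0))
})
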