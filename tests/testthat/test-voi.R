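test_that("largest 6-connected component matches a BFS oracle on random blobs", {
  set.seed(31)
  for (p in c(0.2, 0.35, 0.5)) {
    on <- array(runif(18 * 16 * 14) < p, c(18, 16, 14))
    expect_identical(conjview:::largest_component6(on), largest_component_bfs(on))
  }
})

test_that("body mask separates body from air, keeps the largest blob, fills AP holes", {
  grid <- c(16L, 16L, 12L); spacing <- c(10, 10, 10)
  ph <- build_phantom(phantom_spec(box_body_spec(grid, spacing, bg_ac = 10),
                                   list(organ_spec("kidney", "box", grid * spacing / 2,
                                                   c(20, 20, 20), 10, 30)),
                                   grid_shape = grid, voxel_spacing = spacing))
  bm <- body_mask(ph$activity, threshold = 5 * prod(spacing) / 1000 * 10 / 10)
  expect_identical(bm$voxels, ph$organ_masks$body$voxels)

  # secondary blob dropped, internal AP hole filled
  arr <- array(0, c(12, 12, 10))
  arr[3:9, 3:9, 3:8] <- 10
  arr[5:6, 5:6, 4:5] <- 0                       # internal hole
  arr[11:12, 11:12, 9:10] <- 10                 # small disjoint blob
  bm2 <- body_mask(voxel_grid(arr, c(5, 5, 5)), threshold = 5)
  expect_true(all(bm2$voxels[3:9, 3:9, 3:8]))   # hole filled along AP columns
  expect_false(any(bm2$voxels[11:12, 11:12, 9:10]))

  expect_error(body_mask(voxel_grid(array(1, c(8, 8, 8)), c(1, 1, 1)), 5),
               "threshold")
})

test_that("fraction-of-max segmentation recovers a noiseless phantom kidney", {
  ph <- kidney_in_box_phantom(kidney_ac = 10, bg_ac = 1)
  seed_vox <- round(dim(ph$activity$data) / 2)
  seg <- segment_kidney(ph$activity, seed_vox, frac = 0.5)
  truth <- ph$organ_masks$kidney$voxels
  dice <- 2 * sum(seg$voxels & truth) / (sum(seg$voxels) + sum(truth))
  expect_gte(dice, 0.95)

  # frac = 1 keeps only max-valued voxels: the flat kidney itself
  seg1 <- segment_kidney(ph$activity, seed_vox, frac = 1)
  expect_identical(seg1$voxels, truth)

  # seed in background within probe reach of the kidney: below threshold
  bg_seed <- seed_vox + c(18L, 0L, 0L)          # ~4 cm lateral, outside kidney
  expect_false(truth[bg_seed[1], bg_seed[2], bg_seed[3]])
  expect_error(segment_kidney(ph$activity, bg_seed, frac = 0.5),
               "below the segmentation threshold")
})

test_that("mask projection and body-clipped backprojection behave geometrically", {
  d <- c(24L, 24L, 24L); sp <- c(1, 1, 1)
  one <- array(FALSE, d); one[5, 7, 9] <- TRUE
  roi1 <- project_mask_to_roi(mask3d(one, sp))
  expect_equal(which(roi1$pixels, arr.ind = TRUE), cbind(row = 5L, col = 9L),
               ignore_attr = TRUE)
  col10 <- one; col10[5, 7:16, 9] <- TRUE
  expect_identical(project_mask_to_roi(mask3d(col10, sp))$pixels, roi1$pixels)

  # sphere silhouette is a disc of matching radius (+/- 1 pixel)
  ctr <- c(12.5, 12.5, 12.5); r <- 10
  xs <- seq_len(d[1]) - 0.5
  sph <- outer(outer((xs - ctr[1])^2, (xs - ctr[2])^2, `+`), (xs - ctr[3])^2, `+`) <= r^2
  roi_s <- project_mask_to_roi(mask3d(sph, sp))
  px <- which(roi_s$pixels, arr.ind = TRUE)
  dist <- sqrt((px[, 1] - 0.5 - ctr[1])^2 + (px[, 2] - 0.5 - ctr[3])^2)
  expect_lte(max(dist), r + 1)
  off <- which(!roi_s$pixels, arr.ind = TRUE)
  dist_off <- sqrt((off[, 1] - 0.5 - ctr[1])^2 + (off[, 2] - 0.5 - ctr[3])^2)
  expect_gte(min(dist_off), r - 1)

  # slab body: column voxels = roi pixels x slab thickness in voxels
  slab <- array(FALSE, d); slab[, 4:18, ] <- TRUE
  col <- backproject_roi_to_column(roi_s, mask3d(slab, sp))
  expect_identical(sum(col$voxels), sum(roi_s$pixels) * 15L)

  # ellipsoidal body: per-pixel column length equals the body chord
  body_e <- outer(outer((xs - 12.5)^2 / 11^2, (xs - 12.5)^2 / 9^2, `+`),
                  (xs - 12.5)^2 / 11^2, `+`) <= 1
  col_e <- backproject_roi_to_column(roi_s, mask3d(body_e, sp))
  for (j in sample(nrow(px), 20)) {
    x <- px[j, 1]; z <- px[j, 2]
    expect_identical(sum(col_e$voxels[x, , z]), sum(body_e[x, , z]))
  }
  out_roi <- roi2d(matrix(c(TRUE, rep(FALSE, prod(d[c(1, 3)]) - 1)), d[1]), sp[c(1, 3)])
  expect_error(backproject_roi_to_column(out_roi, mask3d(body_e, sp)),
               "outside the body")

  # project . backproject . project is idempotent on ROIs
  roi_back <- project_mask_to_roi(col_e)
  expect_identical(roi_back$pixels, roi_s$pixels)
})

test_that("true background VOI is the column minus the kidney", {
  d <- c(10L, 12L, 8L); sp <- c(2, 2, 2)
  body <- array(FALSE, d); body[, 2:11, ] <- TRUE
  kid <- array(FALSE, d); kid[4:6, 5:8, 3:5] <- TRUE
  kidm <- mask3d(kid, sp); bodym <- mask3d(body, sp)
  col <- backproject_roi_to_column(project_mask_to_roi(kidm), bodym)
  tb <- true_background_voi(col, kidm)
  expect_identical(sum(tb$voxels), sum(col$voxels) - sum(kid))
  expect_false(any(tb$voxels & kid))
  expect_error(true_background_voi(kidm, col), "not contained")
  expect_warning(true_background_voi(kidm, kidm), "degenerate|empty")

  # on a uniform phantom, TB concentration equals the background truth
  ph <- kidney_in_box_phantom(kidney_ac = 10, bg_ac = 2)
  k <- ph$organ_masks$kidney; b <- ph$organ_masks$body
  colk <- backproject_roi_to_column(project_mask_to_roi(k), b)
  tbk <- true_background_voi(colk, k)
  expect_equal(voi_mean_concentration(ph$activity, tbk), 2, tolerance = 1e-12)
})

test_that("background band geometry and sector assignment follow the convention", {
  px <- matrix(FALSE, 41, 41); px[20, 20] <- TRUE
  rois <- build_background_rois(roi2d(px, c(1, 1)), gap = 2, width = 4)
  expect_named(rois, paste0("B", 1:11))
  get <- function(x, z) {
    hits <- names(rois[1:10])[vapply(rois[1:10], function(r) r$pixels[x, z], TRUE)]
    expect_length(hits, 1)
    hits
  }
  expect_identical(get(20, 24), "B1")   # angle 0 (cranial)
  expect_identical(get(23, 24), "B2")   # atan2(3, 4) = 36.9 deg
  expect_identical(get(24, 20), "B3")   # 90 deg, patient left
  expect_identical(get(20, 16), "B6")   # 180 deg exactly: half-open lower edge
  expect_identical(get(16, 20), "B8")   # 270 deg

  # band pixels sit at Euclidean distance (gap, gap + width] from the ROI
  bp <- which(rois$B11$pixels, arr.ind = TRUE)
  dist <- sqrt((bp[, 1] - 20)^2 + (bp[, 2] - 20)^2)
  expect_true(all(dist > 2 & dist <= 6))
  expect_false(rois$B11$pixels[20, 20])

  # partition: sectors are pairwise disjoint and union to B11, counts exact
  acc <- matrix(0L, 41, 41)
  for (k in 1:10) acc <- acc + rois[[k]]$pixels
  expect_true(all(acc <= 1L))
  expect_identical(acc == 1L, rois$B11$pixels)
  expect_identical(sum(vapply(rois[1:10], function(r) sum(r$pixels), 0L)),
                   sum(rois$B11$pixels))

  edge <- matrix(FALSE, 41, 41); edge[3, 20] <- TRUE
  expect_error(build_background_rois(roi2d(edge, c(1, 1))), "edge")
})

test_that("sector partition also holds for an extended disc-shaped kidney ROI", {
  xs <- seq_len(64) - 0.5
  disc <- outer((xs - 32)^2, (xs - 32)^2, `+`) <= 8^2
  rois <- build_background_rois(roi2d(disc, c(2.21, 4.42)))
  acc <- Reduce(`+`, lapply(rois[1:10], function(r) r$pixels + 0L))
  expect_true(all(acc <= 1L))
  expect_identical(acc == 1L, rois$B11$pixels)
})

test_that("kidney geometry is measured on the centroid transverse slice", {
  d <- c(20L, 30L, 12L); sp <- c(10, 10, 10)
  body <- array(FALSE, d); body[, 5:24, ] <- TRUE          # t_p = 20 cm
  kid <- array(FALSE, d); kid[8:13, 16:19, 5:8] <- TRUE    # t_k = 4 cm
  g <- measure_geometry(mask3d(kid, sp), mask3d(body, sp))
  expect_equal(g$t_k, 4)
  expect_equal(g$t_p, 20)
  expect_equal(g$d_k, 5)                                   # 5 cm dorsal tissue
  expect_equal(g$v_k, sum(kid) * 1000 / 1000)

  kid_back <- array(FALSE, d); kid_back[8:13, 21:24, 5:8] <- TRUE
  gb <- measure_geometry(mask3d(kid_back, sp), mask3d(body, sp))
  expect_equal(gb$d_k, 0)                                  # touching the back

  ph <- kidney_in_box_phantom()
  gk <- measure_geometry(ph$organ_masks$kidney, ph$organ_masks$body)
  expect_lt(abs(gk$v_k - 4 / 3 * pi * 3.3^3) / (4 / 3 * pi * 3.3^3), 0.05)

  span <- array(FALSE, d); span[8:13, 5:24, 5:8] <- TRUE
  expect_error(measure_geometry(mask3d(span, sp), mask3d(body, sp)),
               "whole body")
})
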