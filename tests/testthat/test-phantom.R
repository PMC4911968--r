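test_that("body-only phantom rasterises by voxel-centre inclusion", {
  grid <- c(16L, 16L, 12L); spacing <- c(10, 10, 10)
  body <- organ_spec("body", "ellipsoid", grid * spacing / 2,
                     c(60, 55, 50), ac = 1, hu = 0)
  ph <- build_phantom(phantom_spec(body, list(
    organ_spec("kidney", "ellipsoid", grid * spacing / 2, c(20, 20, 20), 1, 30)),
    grid_shape = grid, voxel_spacing = spacing))
  inside <- ph$organ_masks$body$voxels
  vox_ml <- prod(spacing) / 1000
  expect_true(all(ph$activity$data[inside] == 1 * vox_ml))
  expect_true(all(ph$activity$data[!inside] == 0))
  # voxel-centre membership recomputed independently
  ctr <- grid * spacing / 2
  xs <- (seq_len(grid[1]) - 0.5) * spacing[1]
  q <- outer(outer(((xs - ctr[1]) / 60)^2,
                   (((seq_len(grid[2]) - 0.5) * spacing[2] - ctr[2]) / 55)^2, `+`),
             (((seq_len(grid[3]) - 0.5) * spacing[3] - ctr[3]) / 50)^2, `+`)
  expect_identical(inside, q <= 1)
})

test_that("rasterised kidney volume approximates the analytic ellipsoid volume", {
  ph <- kidney_in_box_phantom(kid_semi = c(33, 33, 33))
  analytic <- 4 / 3 * pi * 3.3^3                       # 150.5 ml
  v <- ph$truth$volume_ml[ph$truth$organ == "kidney"]
  expect_lt(abs(v - analytic) / analytic, 0.05)
})

test_that("later-listed organs overwrite earlier ones in overlaps", {
  grid <- c(16L, 16L, 12L); spacing <- c(10, 10, 10)
  extent <- grid * spacing
  body <- box_body_spec(grid, spacing)
  a <- organ_spec("organA", "box", extent / 2, c(30, 30, 30), 5, 10)
  b <- organ_spec("organB", "box", extent / 2 + c(20, 0, 0), c(30, 30, 30), 9, 20)
  ph <- build_phantom(phantom_spec(body, list(
    organ_spec("kidney", "box", extent / 2, c(10, 10, 10), 9, 30)),
    extra_organs = list(a, b), grid_shape = grid, voxel_spacing = spacing))
  both <- ph$organ_masks$organA$voxels & ph$organ_masks$organB$voxels
  expect_gt(sum(both), 0)
  vox_ml <- prod(spacing) / 1000
  expect_true(all(ph$activity$data[both] == 9 * vox_ml))
})

test_that("invalid phantom specs are rejected", {
  grid <- c(16L, 16L, 12L); spacing <- c(10, 10, 10)
  extent <- grid * spacing
  body <- box_body_spec(grid, spacing)
  outside <- organ_spec("kidney", "box", c(5, 5, 5), c(20, 20, 20), 1, 30)
  expect_error(build_phantom(phantom_spec(body, list(outside), grid_shape = grid,
                                          voxel_spacing = spacing)),
               "outside the body")
  expect_error(phantom_spec(body, list(outside), grid_shape = grid,
                            voxel_spacing = c(0, 1, 1)), "positive")
  expect_error(phantom_spec(body, list(outside), grid_shape = c(4L, 16L, 16L)),
               ">= 8")
  expect_error(organ_spec("k", "box", extent / 2, c(10, 10, 10), ac = -1, hu = 0),
               ">= 0")
})

test_that("truth table matches the ideal volume and is untouched by degradation", {
  ph0 <- kidney_in_box_phantom(kidney_ac = 12, bg_ac = 3)
  ph1 <- kidney_in_box_phantom(kidney_ac = 12, bg_ac = 3,
                               psf_fwhm_mm = 10, poisson = TRUE, seed = 9L)
  expect_identical(ph0$truth, ph1$truth)
  vox_ml <- voxel_volume_ml(ph0$activity)
  for (org in ph0$truth$organ) {
    m <- ph0$organ_masks[[org]]$voxels
    expect_equal(ph0$truth$ac[ph0$truth$organ == org],
                 mean(ph0$activity$data[m]) / vox_ml)
    expect_equal(ph0$truth$volume_ml[ph0$truth$organ == org], sum(m) * vox_ml)
    expect_true(all(m | !m) && !any(m & !ph0$organ_masks$body$voxels))
  }
  expect_equal(ground_truth_ac(ph0, "kidney"), 12)
  expect_error(ground_truth_ac(ph0, "pancreas"), "unknown organ")
  # uniform phantom: background truth equals the stated concentration
  uni <- kidney_in_box_phantom(kidney_ac = 1, bg_ac = 1)
  expect_equal(ground_truth_ac(uni, "body"), 1)
  expect_equal(ground_truth_ac(uni, "kidney"), 1)
})

test_that("fixed seed gives a bit-identical phantom", {
  ph1 <- kidney_in_box_phantom(poisson = TRUE, seed = 4L)
  ph2 <- kidney_in_box_phantom(poisson = TRUE, seed = 4L)
  expect_identical(ph1$observed$data, ph2$observed$data)
  ph3 <- kidney_in_box_phantom(poisson = TRUE, seed = 5L)
  expect_false(identical(ph1$observed$data, ph3$observed$data))
})

test_that("PSF blur conserves counts, has the stated profile, and fwhm 0 is identity", {
  set.seed(11)
  vol <- voxel_grid(array(runif(24^3), c(24, 24, 24)), c(2, 2, 2))
  expect_identical(apply_psf_blur(vol, 0)$data, vol$data)
  out <- apply_psf_blur(vol, 9)
  expect_lt(abs(sum(out$data) - sum(vol$data)) / sum(vol$data), 0.001)
  expect_error(apply_psf_blur(vol, -1), ">= 0")

  # delta impulse: profile matches the closed-form Gaussian at +/- 1 sigma
  d <- c(33L, 33L, 33L)
  imp <- array(0, d); imp[17, 17, 17] <- 1
  fwhm <- 8
  sig <- fwhm / (2 * sqrt(2 * log(2)))       # sigma in voxels (1 mm spacing)
  b <- apply_psf_blur(voxel_grid(imp, c(1, 1, 1)), fwhm)$data
  for (off in c(-3L, 3L)) {                  # ~1 sigma (3.4 voxels)
    expected <- exp(-off^2 / (2 * sig^2))
    expect_lt(abs(b[17 + off, 17, 17] / b[17, 17, 17] - expected) / expected, 0.01)
  }
  expect_lt(abs(sum(b) - 1), 1e-9)
})

test_that("Poisson noise is seeded, mean-preserving, and rejects negatives", {
  z <- voxel_grid(array(0, c(8, 8, 8)), c(1, 1, 1))
  expect_true(all(add_poisson_noise(z, 1)$data == 0))
  u <- voxel_grid(array(100, c(25, 20, 20)), c(1, 1, 1))   # 10^4 voxels
  n1 <- add_poisson_noise(u, 3)
  n2 <- add_poisson_noise(u, 3)
  expect_identical(n1$data, n2$data)
  expect_lt(abs(mean(n1$data) - 100) / 100, 0.01)          # CLT: 3 sd ~ 0.3
  neg <- voxel_grid(array(-1, c(8, 8, 8)), c(1, 1, 1))
  expect_error(add_poisson_noise(neg, 1), ">= 0")
  # RNG state is restored
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(add_poisson_noise(u, 3)); expect_equal(runif(1), before)
})
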