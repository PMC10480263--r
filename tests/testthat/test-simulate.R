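test_that("elastic deformation honours zero displacement, constants and seeds", {
  img <- fix_img32
  p0 <- sim_params(deform_max_disp = 0, deform_grid_spacing = 8)
  expect_equal(elastic_deform(img, p0, seed = 5), img)

  const <- matrix(123.4, 32, 32)
  expect_equal(elastic_deform(const, fix_params32, seed = 3), const)

  a <- elastic_deform(img, fix_params32, seed = 3)
  expect_identical(a, elastic_deform(img, fix_params32, seed = 3))
  expect_gt(max(abs(a - elastic_deform(img, fix_params32, seed = 4))), 0)

  bad <- sim_params(deform_grid_spacing = 64)
  expect_error(elastic_deform(img, bad, seed = 1), "grid_spacing")
})

test_that("forward projection conserves mass and centres point sources", {
  # with the offset equal to minus the air level, an all-air image
  # projects to an exactly zero sinogram
  air <- matrix(-1000, 32, 32)
  p <- sim_params(n_angles = 45, attenuation_offset = 1000)
  s <- forward_project(air, p)
  expect_true(all(s$values == 0))

  # centred disc: total projected mass is identical at every angle
  disc <- matrix(-1000, 64, 64)
  disc[oracle_ellipse_mask(64, c(32.5, 32.5), c(20, 20))] <- 0
  sd_ <- forward_project(disc, sim_params(n_angles = 60))
  sums <- rowSums(sd_$values)
  expect_lt((max(sums) - min(sums)) / mean(sums), 0.01)

  # single hot pixel at the exact grid centre projects to the central bin
  hot <- matrix(0, 33, 33)
  hot[17, 17] <- 1000
  sh <- forward_project(hot, sim_params(n_angles = 30,
                                        attenuation_offset = 0))
  central_bin <- (ncol(sh$values) + 1) / 2
  expect_true(all(apply(sh$values, 1, which.max) == central_bin))
})

test_that("sinogram mixing respects the replacement bound and degenerate cases", {
  s <- forward_project(fix_img32, fix_params32)
  dist <- elastic_deform(fix_img32, fix_params32, seed = 2)
  sd_ <- forward_project(dist, fix_params32)

  none <- mix_sinograms(s, sd_, sim_params(max_replace_fraction = 0,
                                           n_angles = fix_params32$n_angles),
                        seed = 4)
  expect_identical(none$sinogram$values, s$values)
  expect_identical(none$replaced_fraction, 0)

  self <- mix_sinograms(s, s, fix_params32, seed = 4)
  expect_identical(self$sinogram$values, s$values)

  mx <- mix_sinograms(s, sd_, fix_params32, seed = 11)
  expect_lte(mean(mx$sinogram$values != s$values), 0.10)
  expect_lte(mx$replaced_fraction, 0.10)

  bad <- structure(list(values = s$values[, -1], angles = s$angles),
                   class = "sinogram")
  expect_error(mix_sinograms(s, bad, fix_params32, seed = 1), "dimensions")
})

test_that("filtered back-projection inverts the projection within tolerance", {
  # zero sinogram reconstructs to the clamp of (0 - offset)
  z <- structure(list(values = matrix(0, 45, 47), angles = seq(0, 176, 4)),
                 class = "sinogram")
  rec0 <- back_project(z, 32, sim_params())
  expect_true(all(rec0 == -1024))

  # round trip on the smooth phantom: interior MAE below the calibrated
  # 60 HU tolerance of this ramp-filtered reconstruction
  img <- fix_img128
  s <- forward_project(img, fix_params128)
  rec <- back_project(s, 128, fix_params128)
  spec <- fix_spec128
  interior <- oracle_ellipse_mask(128, spec$body_centre, 0.9 * spec$body_axes)
  expect_lt(mean(abs(rec[interior] - img[interior])), 60)
})

test_that("streak severity grows with the forced replacement fraction", {
  img <- fix_img128
  p <- fix_params128
  s_o <- forward_project(img, p)
  s_d <- forward_project(elastic_deform(img, p, seed = 6), p)
  clean <- back_project(s_o, 128, p)
  n <- length(s_o$values)
  set.seed(99)
  perm <- sample.int(n)  # nested entry sets: smaller fractions are subsets
  maes <- vapply(c(0, 0.02, 0.05, 0.10), function(f) {
    v <- s_o$values
    k <- round(f * n)
    if (k > 0) v[perm[seq_len(k)]] <- s_d$values[perm[seq_len(k)]]
    mixed <- structure(list(values = v, angles = s_o$angles),
                       class = "sinogram")
    mean(abs(back_project(mixed, 128, p) - clean))
  }, numeric(1))
  expect_identical(maes[1], 0)
  expect_true(all(diff(maes) > 0))
})

test_that("isocentre sampling enforces the partial-acquisition rule", {
  small <- matrix(FALSE, 64, 64)
  small[oracle_ellipse_mask(64, c(32, 32), c(5, 5))] <- TRUE
  expect_error(sample_isocentre(small, sim_params(fov_radius = 128), seed = 1),
               "cannot truncate")

  bm <- body_mask(fix_img128)
  iso <- sample_isocentre(bm, fix_params128, seed = 5)
  idx <- which(bm, arr.ind = TRUE)
  outside <- sum((idx[, 1] - iso$row)^2 + (idx[, 2] - iso$col)^2 >
                   fix_params128$fov_radius^2)
  expect_gte(outside, fix_params128$min_outside_fraction * nrow(idx))
  expect_identical(iso, sample_isocentre(bm, fix_params128, seed = 5))
})

test_that("the FOV mask zeroes exactly the pixels beyond the radius", {
  img <- fix_img32
  # radius covering the whole image from the centre: unchanged
  big <- sim_params(fov_radius = 1000)
  expect_identical(apply_fov_mask(img, list(row = 16, col = 16), big), img)

  ones <- matrix(1, 128, 128)
  p <- sim_params(fov_radius = 32)
  masked <- apply_fov_mask(ones, list(row = 64, col = 64), p)
  r <- matrix(seq_len(128), 128, 128)
  c <- matrix(seq_len(128), 128, 128, byrow = TRUE)
  inside <- (r - 64)^2 + (c - 64)^2 <= 32^2
  expect_identical(sum(masked != 0), sum(inside))
  d <- sqrt((r - 64)^2 + (c - 64)^2)
  expect_lte(max(d[masked != 0]), 32)
  expect_error(apply_fov_mask(img, list(row = 99, col = 1), p), "outside")
})

test_that("the full simulation chain yields consistent, seeded pairs", {
  pair <- simulate_scbct_slice(fix_img128, fix_params128, seed = 3)
  expect_identical(pair, simulate_scbct_slice(fix_img128, fix_params128,
                                              seed = 3))
  r <- matrix(seq_len(128), 128, 128)
  c <- matrix(seq_len(128), 128, 128, byrow = TRUE)
  outside <- (r - pair$isocentre$row)^2 + (c - pair$isocentre$col)^2 >
    fix_params128$fov_radius^2
  expect_true(all(pair$scbct[outside] == 0))
  expect_true(all(pair$streak_gt[outside] == 0))
  fov <- !outside
  expect_gt(mean(abs(pair$scbct[fov] - pair$streak_gt[fov])), 0)
  expect_identical(mean(abs(pair$streak_gt[fov] - pair$full_gt[fov])), 0)
  expect_identical(pair$full_gt, fix_img128)
  expect_lte(pair$replaced_fraction, fix_params128$max_replace_fraction)

  vol <- ct_volume(list(fix_img128, fix_img128), 3, "PX")
  sim <- simulate_scbct_volume(vol, fix_params128, seed = 2)
  expect_length(sim$pairs, 2)
  expect_identical(n_slices(sim$cbct), 2L)
  # per-slice seeds differ, so the two slices are streaked differently
  expect_gt(max(abs(sim$cbct$slices[[1]] - sim$cbct$slices[[2]])), 0)
})
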