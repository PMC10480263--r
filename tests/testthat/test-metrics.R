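test_that("SSIM identities, symmetry and bounds hold", {
  set.seed(1)
  img <- matrix(runif(32 * 32, -1000, 2000), 32)
  expect_equal(ssim_slice(img, img), 1)
  noisy <- img + matrix(rnorm(32 * 32, 0, 300), 32)
  expect_lt(ssim_slice(img, noisy), 1)
  expect_equal(ssim_slice(img, noisy), ssim_slice(noisy, img))
  for (k in 1:5) {
    a <- matrix(runif(15 * 15, -1024, 3071), 15)
    b <- matrix(runif(15 * 15, -1024, 3071), 15)
    v <- ssim_slice(a, b)
    expect_gte(v, -1); expect_lte(v, 1)
  }
  expect_error(ssim_slice(img, img[, -1]), "dimensions")
  expect_error(ssim_slice(img[1:8, 1:8], img[1:8, 1:8]), "window")
})

test_that("SSIM agrees with a brute-force windowed evaluation", {
  set.seed(2)
  a <- matrix(runif(12 * 12, -1024, 3071), 12)
  b <- a + matrix(rnorm(12 * 12, 0, 200), 12)
  expect_equal(ssim_slice(a, b, window_size = 5, sigma = 1.5),
               oracle_ssim(a, b, window = 5, sigma = 1.5),
               tolerance = 1e-12)
  # masked variant averages only over window centres inside the mask
  mask <- matrix(FALSE, 12, 12); mask[4:9, 4:9] <- TRUE
  expect_equal(ssim_slice(a, b, window_size = 5, mask = mask),
               local({
                 sm <- matrix(NA_real_, 8, 8)
                 for (i in 1:8) for (j in 1:8)
                   sm[i, j] <- oracle_ssim(a[i:(i + 4), j:(j + 4)],
                                           b[i:(i + 4), j:(j + 4)], window = 5)
                 mean(sm[mask[3:10, 3:10]])
               }),
               tolerance = 1e-12)
})

test_that("MAE matches an elementwise oracle and obeys the triangle inequality", {
  img <- fix_img32
  expect_identical(mae_slice(img, img), 0)
  expect_equal(mae_slice(img, img + 5), 5)
  set.seed(3)
  a <- matrix(runif(256, -1024, 3071), 16)
  b <- matrix(runif(256, -1024, 3071), 16)
  oracle <- sum(abs(a - b)) / length(a)
  expect_equal(mae_slice(a, b), oracle)
  for (k in 1:5) {
    x <- matrix(runif(64), 8); y <- matrix(runif(64), 8)
    z <- matrix(runif(64), 8)
    expect_lte(mae_slice(x, z), mae_slice(x, y) + mae_slice(y, z) + 1e-12)
  }
})

test_that("difference maps are signed truth-minus-output and antisymmetric", {
  img <- fix_img32
  expect_true(all(difference_map(img, img) == 0))
  expect_true(all(difference_map(img - 10, img) == 10))
  other <- img + matrix(rnorm(length(img)), nrow(img))
  expect_equal(difference_map(other, img), -difference_map(img, other))
  f <- tempfile(fileext = ".png")
  plot_difference_map(difference_map(other, img), f)
  expect_true(file.exists(f))
})

test_that("volume evaluation aggregates per-slice metrics correctly", {
  vol <- ct_volume(list(fix_img32, fix_img32 + 1, fix_img32 - 3), 3, "P")
  self <- evaluate_volume(vol, vol, "self")
  expect_equal(self$mean_ssim, 1)
  expect_equal(self$sd_ssim, 0)
  expect_equal(self$mean_mae, 0)

  truth <- ct_volume(list(fix_img32, fix_img32, fix_img32), 3, "P")
  pred <- ct_volume(list(fix_img32 + 1, fix_img32 + 2, fix_img32 + 3), 3, "P")
  rep <- evaluate_volume(pred, truth, "shifted")
  expect_equal(rep$per_slice$mae, c(1, 2, 3))
  expect_equal(rep$mean_mae, 2)
  expect_equal(rep$sd_mae, 1)
  # summary statistics equal direct recomputation from the per-slice table
  expect_equal(rep$mean_ssim, mean(rep$per_slice$ssim))
  expect_equal(rep$sd_ssim, sd(rep$per_slice$ssim))
  # aggregation is permutation-invariant
  pred_rev <- ct_volume(rev(pred$slices), 3, "P")
  truth_rev <- ct_volume(rev(truth$slices), 3, "P")
  rep_rev <- evaluate_volume(pred_rev, truth_rev, "shifted")
  expect_equal(rep_rev$mean_mae, rep$mean_mae)
  expect_equal(rep_rev$sd_mae, rep$sd_mae)
  expect_error(evaluate_volume(ct_volume(pred$slices[1:2], 3, "P"), truth),
               "slice counts")
})

test_that("report tables keep label order, column order and CSV precision", {
  vol <- ct_volume(list(fix_img32), 3, "P")
  reps <- list(evaluate_volume(vol, vol, "Regular CBCT"),
               evaluate_volume(ct_volume(list(fix_img32 + 2), 3, "P"), vol,
                               "Patient-specific model 1"),
               evaluate_volume(ct_volume(list(fix_img32 + 7), 3, "P"), vol,
                               "Patient-specific model 2"))
  tab <- compare_reports(reps)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$image_volume,
                   c("Regular CBCT", "Patient-specific model 1",
                     "Patient-specific model 2"))
  expect_identical(names(tab),
                   c("image_volume", "ssim", "ssim_sd", "mae", "mae_sd"))
  f <- tempfile(fileext = ".csv")
  compare_reports(reps, file = f)
  back <- read.csv(f)
  expect_equal(as.numeric(back$mae), tab$mae, tolerance = 1e-5)
  expect_equal(as.numeric(back$ssim), tab$ssim, tolerance = 1e-5)
})
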