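gaussian_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Structural similarity between two slices
#'
#' Standard SSIM with a Gaussian window (default 11 x 11, sigma 1.5),
#' stability constants `K1 = 0.01`, `K2 = 0.03`, and a fixed
#' `data_range` of 4095 (the full HU span), so values are comparable
#' across slices. The SSIM map is averaged over all fully valid windows;
#' an optional mask restricts the average to windows whose centre lies
#' in the mask. Symmetric in its two arguments.
#'
#' @param a,b numeric matrices with identical dimensions.
#' @param window_size odd window width in px.
#' @param sigma Gaussian window standard deviation.
#' @param K1,K2 stability constants.
#' @param data_range intensity span `L` in the SSIM constants.
#' @param mask optional logical matrix (same size as `a`).
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim_slice <- function(a, b, window_size = 11, sigma = 1.5,
                       K1 = 0.01, K2 = 0.03, data_range = 4095,
                       mask = NULL) {
  if (!identical(dim(a), dim(b))) stop("image dimensions do not match")
  if (window_size %% 2 != 1) stop("'window_size' must be odd")
  if (any(dim(a) < window_size))
    stop("images are smaller than the SSIM window")
  w <- gaussian_kernel(window_size, sigma)
  mu_a <- cpp_conv2_valid(a, w)
  mu_b <- cpp_conv2_valid(b, w)
  saa <- cpp_conv2_valid(a * a, w) - mu_a^2
  sbb <- cpp_conv2_valid(b * b, w) - mu_b^2
  sab <- cpp_conv2_valid(a * b, w) - mu_a * mu_b
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  smap <- ((2 * mu_a * mu_b + C1) * (2 * sab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (saa + sbb + C2))
  if (is.null(mask)) return(mean(smap))
  half <- (window_size - 1) / 2
  m <- mask[(half + 1):(nrow(a) - half), (half + 1):(ncol(a) - half)]
  if (!any(m)) stop("mask contains no valid window centres")
  mean(smap[m])
}

#' Mean absolute error between two slices
#'
#' @param a,b numeric matrices (HU) with identical dimensions.
#' @param mask optional logical matrix restricting the average.
#' @return scalar MAE in HU.
#' @export
mae_slice <- function(a, b, mask = NULL) {
  if (!identical(dim(a), dim(b))) stop("image dimensions do not match")
  d <- abs(a - b)
  if (is.null(mask)) mean(d) else mean(d[mask])
}

#' Signed difference map
#'
#' Computes `truth - output` in HU, the convention used for the
#' difference panels (positive where the model under-estimates
#' intensity).
#'
#' @param output model output slice.
#' @param truth ground-truth slice.
#' @return signed HU matrix.
#' @export
difference_map <- function(output, truth) {
  if (!identical(dim(output), dim(truth)))
    stop("image dimensions do not match")
  truth - output
}

#' Render a difference map to PNG
#'
#' Symmetric diverging colour scale about 0 HU (blue negative, white
#' zero, red positive).
#'
#' @param map signed HU matrix from [difference_map()].
#' @param file output PNG path.
#' @param limit colour scale limit in HU; defaults to the maximum
#'   absolute value of the map.
#' @return the file path, invisibly.
#' @export
plot_difference_map <- function(map, file, limit = NULL) {
  if (is.null(limit)) limit <- max(abs(map), 1e-9)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(255)
  grDevices::png(file, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2, 2, 2, 4))
  graphics::image(t(map[nrow(map):1, ]), col = pal,
                  zlim = c(-limit, limit), axes = FALSE,
                  main = "difference (HU)")
  invisible(file)
}

#' Evaluate a predicted volume against ground truth
#'
#' Computes per-slice SSIM and MAE and aggregates them into the
#' volume-level mean and sample standard deviation (n - 1), the shape
#' used to compare regular CBCT and patient-specific model outputs.
#'
#' @param pred,truth [ct_volume()] objects with equal slice counts and
#'   dimensions.
#' @param label report label (e.g. "Regular CBCT").
#' @param mask optional logical matrix applied to every slice
#'   (field-of-view / body-only evaluation).
#' @param ... further arguments passed to [ssim_slice()].
#' @return object of class `metrics_report` with `per_slice`
#'   (data.frame: slice_index, ssim, mae), `mean_ssim`, `sd_ssim`,
#'   `mean_mae`, `sd_mae`, `label`.
#' @export
evaluate_volume <- function(pred, truth, label = "volume", mask = NULL, ...) {
  if (n_slices(pred) != n_slices(truth))
    stop("slice counts do not match")
  if (!identical(slice_dim(pred), slice_dim(truth)))
    stop("slice dimensions do not match")
  per <- data.frame(
    slice_index = seq_len(n_slices(pred)),
    ssim = vapply(seq_len(n_slices(pred)), function(i)
      ssim_slice(pred$slices[[i]], truth$slices[[i]], mask = mask, ...),
      numeric(1)),
    mae = vapply(seq_len(n_slices(pred)), function(i)
      mae_slice(pred$slices[[i]], truth$slices[[i]], mask = mask),
      numeric(1))
  )
  structure(
    list(per_slice = per,
         mean_ssim = mean(per$ssim),
         sd_ssim = if (nrow(per) > 1) sd(per$ssim) else 0,
         mean_mae = mean(per$mae),
         sd_mae = if (nrow(per) > 1) sd(per$mae) else 0,
         label = label),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s (%d slices)\n", x$label,
              nrow(x$per_slice)))
  cat(sprintf("  SSIM %.4f (sd %.3g)   MAE %.2f HU (sd %.3g)\n",
              x$mean_ssim, x$sd_ssim, x$mean_mae, x$sd_mae))
  invisible(x)
}

#' Tabulate metric reports
#'
#' Renders one row per report in the column order: image volume, SSIM,
#' its standard deviation, MAE, its standard deviation. Optionally
#' written as CSV.
#'
#' @param reports list of `metrics_report` objects.
#' @param file optional CSV path.
#' @return data.frame with columns `image_volume`, `ssim`, `ssim_sd`,
#'   `mae`, `mae_sd`.
#' @export
compare_reports <- function(reports, file = NULL) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  out <- do.call(rbind, lapply(reports, function(r)
    data.frame(image_volume = r$label, ssim = r$mean_ssim,
               ssim_sd = r$sd_ssim, mae = r$mean_mae, mae_sd = r$sd_mae)))
  if (!is.null(file)) write.csv(format(out, digits = 6), file,
                                row.names = FALSE)
  out
}
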