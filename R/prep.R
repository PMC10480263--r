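#' Zero-pad a CBCT slice onto a larger grid
#'
#' Centres the slice on a `target_size` square grid; every added pixel is
#' exactly 0 and the original content is preserved verbatim. Padding with
#' zeros is what allows the (larger-coverage) planning CT to be
#' registered onto the CBCT grid.
#'
#' @param cbct matrix.
#' @param target_size pixels per side of the padded grid; must be at
#'   least as large as both input dimensions.
#' @return `target_size x target_size` matrix.
#' @export
pad_to_grid <- function(cbct, target_size) {
  h <- nrow(cbct); w <- ncol(cbct)
  if (target_size < h || target_size < w)
    stop("'target_size' must be at least as large as the input")
  if (h == target_size && w == target_size) return(cbct)
  out <- matrix(0, target_size, target_size)
  r0 <- floor((target_size - h) / 2)
  c0 <- floor((target_size - w) / 2)
  out[r0 + seq_len(h), c0 + seq_len(w)] <- cbct
  out
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# Resample `moving` on the grid of a fixed image of dims out_dim under a
# rigid + isotropic-scale transform (rotation about the grid centre,
# then scaling, then translation t = c(tr, tc)).
resample_rigid <- function(moving, rot_deg, tr, tc, scale, out_dim) {
  h <- out_dim[1]; w <- out_dim[2]
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  r <- matrix(seq_len(h), h, w) - ctr[1] - tr
  c <- matrix(seq_len(w), h, w, byrow = TRUE) - ctr[2] - tc
  Rinv <- rot2(-rot_deg)
  src_r <- (Rinv[1, 1] * r + Rinv[1, 2] * c) / scale + (nrow(moving) + 1) / 2
  src_c <- (Rinv[2, 1] * r + Rinv[2, 2] * c) / scale + (ncol(moving) + 1) / 2
  v <- cpp_bilinear_sample(moving, as.vector(src_r) - 1, as.vector(src_c) - 1,
                           "zero")
  matrix(v, h, w)
}

downsample2 <- function(img, k) {
  if (k == 1) return(img)
  h <- floor(nrow(img) / k) * k
  w <- floor(ncol(img) / k) * k
  x <- img[seq_len(h), seq_len(w)]
  # block-mean pooling
  x <- (array(x, c(k, h / k, w)) |> colMeans())
  x <- aperm(array(x, c(h / k, k, w / k)), c(1, 3, 2))
  rowMeans(x, dims = 2)
}

#' Rigidly register a CT slice to a padded CBCT slice
#'
#' Optimises a 2-D rigid transform plus isotropic scale (the "resize")
#' by maximising the Pearson correlation between the resampled CT and
#' the CBCT, computed only over the nonzero (field-of-view) region of
#' the CBCT so that the zero padding cannot bias the alignment.
#' Multi-resolution Nelder-Mead refinement.
#'
#' @param moving_ct CT slice (matrix).
#' @param fixed_cbct padded CBCT slice (matrix) with nonzero content.
#' @param config optional list: `levels` (downsampling factors, coarse to
#'   fine; default `c(4, 2, 1)`), `maxit` per level (default 300),
#'   `init` (initial `c(rot_deg, tr, tc, scale)`).
#' @return object of class `registration_result`: list with `transform`
#'   (`rotation` deg, `translation` c(row, col) px, `scale`),
#'   `resampled_ct`, and `final_metric` (correlation in the FOV).
#' @export
register_ct_to_cbct <- function(moving_ct, fixed_cbct, config = list()) {
  if (all(fixed_cbct == 0)) stop("fixed CBCT has no nonzero content")
  levels <- config$levels %||% c(4, 2, 1)
  maxit <- config$maxit %||% 300
  par <- config$init %||% c(0, 0, 0, 1)  # rot, tr, tc, scale
  for (k in levels) {
    if (min(dim(fixed_cbct)) / k < 16) next
    fx <- downsample2(fixed_cbct, k)
    mv <- downsample2(moving_ct, k)
    mask <- fx != 0
    if (sum(mask) < 32) next
    obj <- function(p) {
      res <- resample_rigid(mv, p[1], p[2], p[3], max(p[4], 1e-3), dim(fx))
      v <- suppressWarnings(cor(res[mask], fx[mask]))
      if (!is.finite(v)) return(1)
      -v
    }
    p0 <- c(par[1], par[2] / k, par[3] / k, par[4])
    fit <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit,
                                parscale = c(1, 2 / k, 2 / k, 0.02)))
    par <- c(fit$par[1], fit$par[2] * k, fit$par[3] * k, fit$par[4])
  }
  res <- resample_rigid(moving_ct, par[1], par[2], par[3], par[4],
                        dim(fixed_cbct))
  mask <- fixed_cbct != 0
  metric <- suppressWarnings(cor(res[mask], fixed_cbct[mask]))
  if (!is.finite(metric))
    stop("registration failed to produce a finite similarity (last metric NA)")
  structure(
    list(transform = list(rotation = par[1],
                          translation = c(row = par[2], col = par[3]),
                          scale = par[4]),
         resampled_ct = res, final_metric = metric),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  t <- x$transform
  cat(sprintf(paste0("<registration_result> rotation %.3f deg, translation ",
                     "(%.2f, %.2f) px, scale %.4f, metric %.4f\n"),
              t$rotation, t$translation[1], t$translation[2], t$scale,
              x$final_metric))
  invisible(x)
}

#' Detect the couch top surface
#'
#' Scans the rows below the lowest extent of the body mask for the first
#' row whose above-air (> -900 HU) run spans at least 60% of the image
#' width; that row is taken as the couch top. If no such row exists, a
#' configured fallback row is used.
#'
#' @param ct HU-valued matrix.
#' @param config optional list with `couch_row` fallback.
#' @return integer row index (1-based).
#' @export
detect_couch_surface <- function(ct, config = list()) {
  bm <- body_mask(ct)
  body_rows <- which(apply(bm, 1, any))
  start <- if (length(body_rows)) max(body_rows) + 1L else 1L
  w <- ncol(ct)
  if (start <= nrow(ct)) {
    for (r in start:nrow(ct)) {
      if (sum(ct[r, ] > -900) >= 0.6 * w) return(r)
    }
  }
  if (!is.null(config$couch_row)) return(as.integer(config$couch_row))
  stop("no couch surface found and no fallback 'couch_row' configured")
}

#' Remove the treatment couch from a CT slice
#'
#' Assigns -1024 HU to every pixel strictly below the couch surface row
#' (larger row index, i.e. posterior in supine head-first display
#' convention); all rows at or above `couch_row` are untouched.
#'
#' @param ct HU-valued matrix.
#' @param couch_row 1-based row index of the couch top surface.
#' @return matrix with the couch region set to -1024.
#' @export
remove_couch <- function(ct, couch_row) {
  if (couch_row < 1 || couch_row > nrow(ct))
    stop("'couch_row' must lie within the image")
  if (couch_row < nrow(ct))
    ct[(couch_row + 1L):nrow(ct), ] <- -1024
  ct
}

#' Build paired training samples from a CT and CBCT volumes
#'
#' For each CBCT slice: zero-pad to the target grid, rigidly register the
#' corresponding CT slice onto it (optional when the volumes were
#' constructed on a common grid), and remove the couch from the target.
#' Slice pairing is index-aligned, which is only meaningful when both
#' sets share slice thickness; a mismatch is an error.
#'
#' @param ct_vol planning-CT [ct_volume()].
#' @param cbct_vols list of setup-CBCT [ct_volume()] objects.
#' @param config list: `target_size` (default = CT slice size),
#'   `register` (default TRUE), `couch_row` (fallback/override),
#'   `detect_couch` (default TRUE), `stage_tag` label.
#' @return list of `paired_sample` objects (fields `input_img`,
#'   `target_img`, `patient_id`, `slice_index`, `stage_tag`).
#' @export
build_training_pairs <- function(ct_vol, cbct_vols, config = list()) {
  if (inherits(cbct_vols, "ct_volume")) cbct_vols <- list(cbct_vols)
  for (v in cbct_vols) {
    if (!isTRUE(all.equal(v$slice_thickness, ct_vol$slice_thickness)))
      stop("slice thickness mismatch between CT and CBCT volumes: ",
           "both image sets must share slice thickness")
    if (n_slices(v) != n_slices(ct_vol))
      stop("slice count mismatch between CT and CBCT volumes")
  }
  target_size <- config$target_size %||% max(slice_dim(ct_vol))
  register <- config$register %||% TRUE
  stage_tag <- config$stage_tag %||% "clinical"
  pairs <- list()
  for (vi in seq_along(cbct_vols)) {
    v <- cbct_vols[[vi]]
    for (i in seq_len(n_slices(v))) {
      cbct_p <- pad_to_grid(v$slices[[i]], target_size)
      target <- if (isTRUE(register)) {
        register_ct_to_cbct(ct_vol$slices[[i]], cbct_p, config)$resampled_ct
      } else {
        pad_to_grid(ct_vol$slices[[i]], target_size)
      }
      row <- if (!is.null(config$couch_row) && !isTRUE(config$detect_couch))
        as.integer(config$couch_row)
      else
        detect_couch_surface(target, config)
      target <- remove_couch(target, row)
      pairs[[length(pairs) + 1L]] <- structure(
        list(input_img = cbct_p, target_img = target,
             patient_id = ct_vol$patient_id, slice_index = i,
             stage_tag = paste0(stage_tag, "-set", vi)),
        class = "paired_sample"
      )
    }
  }
  pairs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
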