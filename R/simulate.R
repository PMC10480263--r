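#' Parameters of the synthetic-CBCT simulator
#'
#' Houses the constants of the simulation chain: elastic deformation,
#' forward projection, partial sinogram replacement (at most
#' `max_replace_fraction` of entries, drawn uniformly per image),
#' filtered back-projection, and circular field-of-view truncation at
#' `fov_radius` about a lateralised isocentre. At the clinical 512 px
#' scale the FOV radius is 128 px; `desk_sim_params()` scales the
#' geometry down proportionally for fast CPU runs.
#'
#' @param max_replace_fraction upper bound on the fraction of sinogram
#'   entries replaced by the distorted sinogram; default 0.10.
#' @param fov_radius field-of-view radius in px; default 128.
#' @param n_angles number of projection angles over `[0, 180)`.
#' @param deform_grid_spacing coarse displacement-grid spacing, px.
#' @param deform_max_disp maximum nodal displacement, px.
#' @param min_outside_fraction minimum fraction of body pixels that must
#'   fall outside the FOV for an isocentre to be accepted.
#' @param attenuation_offset HU shift applied before projection so air
#'   contributes ~0 attenuation; default +1024.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(max_replace_fraction = 0.10, fov_radius = 128,
                       n_angles = 180, deform_grid_spacing = 64,
                       deform_max_disp = 15, min_outside_fraction = 0.05,
                       attenuation_offset = 1024) {
  if (max_replace_fraction < 0 || max_replace_fraction > 1)
    stop("'max_replace_fraction' must lie in [0, 1]")
  if (fov_radius <= 0) stop("'fov_radius' must be positive")
  if (n_angles < 2) stop("'n_angles' must be at least 2")
  if (min_outside_fraction <= 0 || min_outside_fraction >= 1)
    stop("'min_outside_fraction' must lie in (0, 1)")
  structure(
    list(max_replace_fraction = max_replace_fraction, fov_radius = fov_radius,
         n_angles = n_angles, deform_grid_spacing = deform_grid_spacing,
         deform_max_disp = deform_max_disp,
         min_outside_fraction = min_outside_fraction,
         attenuation_offset = attenuation_offset),
    class = "sim_params"
  )
}

#' @rdname sim_params
#' @param image_size pixel size of the desk-scale images.
#' @export
desk_sim_params <- function(image_size = 128) {
  sim_params(fov_radius = image_size / 4,
             n_angles = 90,
             deform_grid_spacing = max(8, image_size / 8),
             deform_max_disp = max(2, round(15 * image_size / 512)))
}

projection_angles <- function(params) {
  seq(0, 180, length.out = params$n_angles + 1)[seq_len(params$n_angles)]
}

sinogram_bins <- function(h, w) 2L * ceiling(sqrt(2) * max(h, w) / 2) + 1L

#' Random elastic deformation of a slice
#'
#' Draws per-node displacements uniform in
#' `[-deform_max_disp, +deform_max_disp]` on a coarse grid of spacing
#' `deform_grid_spacing`, interpolates the field bilinearly to pixel
#' resolution, and warps the image with bilinear sampling and edge
#' clamping. Deterministic per seed.
#'
#' @param img HU-valued matrix.
#' @param params [sim_params()].
#' @param seed integer seed.
#' @return deformed matrix, same dimensions.
#' @export
elastic_deform <- function(img, params = sim_params(), seed = 1L) {
  h <- nrow(img); w <- ncol(img)
  g <- params$deform_grid_spacing
  if (g >= min(h, w))
    stop("'deform_grid_spacing' must be smaller than the image size")
  set.seed(derive_seed(seed, "deform"))
  nr <- floor((h - 1) / g) + 2L
  nc <- floor((w - 1) / g) + 2L
  m <- params$deform_max_disp
  dr_nodes <- matrix(runif(nr * nc, -m, m), nr, nc)
  dc_nodes <- matrix(runif(nr * nc, -m, m), nr, nc)
  rr <- matrix((seq_len(h) - 1) / g, h, w)
  cc <- matrix((seq_len(w) - 1) / g, h, w, byrow = TRUE)
  dr <- cpp_bilinear_sample(dr_nodes, as.vector(rr), as.vector(cc), "clamp")
  dc <- cpp_bilinear_sample(dc_nodes, as.vector(rr), as.vector(cc), "clamp")
  rows0 <- matrix(seq_len(h) - 1, h, w)
  cols0 <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  out <- cpp_bilinear_sample(img, as.vector(rows0) + dr,
                             as.vector(cols0) + dc, "clamp")
  matrix(out, h, w)
}

#' Forward (radon) projection of a slice
#'
#' Shifts intensities by `attenuation_offset` (so air at -1024 HU maps to
#' approximately zero attenuation) and computes parallel-beam line
#' integrals over the configured projection angles.
#'
#' @inheritParams elastic_deform
#' @return object of class `sinogram`: list with `values`
#'   (`n_angles x n_bins` matrix) and `angles` (degrees).
#' @export
forward_project <- function(img, params = sim_params()) {
  angles <- projection_angles(params)
  nb <- sinogram_bins(nrow(img), ncol(img))
  vals <- cpp_radon(img + params$attenuation_offset, angles, nb)
  structure(list(values = vals, angles = angles), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d bins, range [%.1f, %.1f]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Partial sinogram replacement
#'
#' Draws a replacement fraction `f ~ Uniform(0, max_replace_fraction)`,
#' selects `round(f * N)` entry positions uniformly without replacement
#' (`N` = total sinogram entries), and copies those entries from the
#' distorted sinogram into a copy of the original. Entry-wise replacement
#' of inconsistent projection data is what produces streaks after
#' reconstruction.
#'
#' @param s_orig,s_dist congruent `sinogram` objects (original and
#'   elastically distorted image).
#' @param params [sim_params()].
#' @param seed integer seed.
#' @return list with `sinogram` (mixed) and `replaced_fraction` (the
#'   realised `round(f * N) / N`).
#' @export
mix_sinograms <- function(s_orig, s_dist, params = sim_params(), seed = 1L) {
  if (!identical(dim(s_orig$values), dim(s_dist$values)))
    stop("sinogram dimensions do not match")
  set.seed(derive_seed(seed, "mix"))
  n <- length(s_orig$values)
  f <- runif(1, 0, params$max_replace_fraction)
  k <- round(f * n)
  out <- s_orig$values
  if (k > 0) {
    idx <- sample.int(n, k)
    out[idx] <- s_dist$values[idx]
  }
  list(sinogram = structure(list(values = out, angles = s_orig$angles),
                            class = "sinogram"),
       replaced_fraction = k / n)
}

ramp_filter_rows <- function(vals) {
  nb <- ncol(vals)
  L <- 2^ceiling(log2(2 * nb))
  # spatial-domain Ram-Lak filter (unit detector spacing)
  h <- numeric(L)
  h[1] <- 0.25
  k <- seq_len(L / 2)
  odd <- k %% 2 == 1
  h[1 + k[odd]] <- -1 / (pi^2 * k[odd]^2)
  h[L + 1 - k[odd & k < L / 2]] <- -1 / (pi^2 * k[odd & k < L / 2]^2)
  f_ramp <- 2 * Re(stats::fft(h))
  out <- matrix(0, nrow(vals), nb)
  for (a in seq_len(nrow(vals))) {
    p <- c(vals[a, ], numeric(L - nb))
    q <- Re(stats::fft(stats::fft(p) * f_ramp, inverse = TRUE)) / L
    out[a, ] <- q[seq_len(nb)]
  }
  out
}

#' Filtered back-projection reconstruction
#'
#' Ramp-filters each projection (Ram-Lak, linear interpolation during
#' backprojection), reconstructs on an `out_size` grid, removes the
#' attenuation offset and clamps to the HU range `[-1024, 3071]`.
#'
#' @param s a `sinogram`.
#' @param out_size output grid size in px (square).
#' @param params [sim_params()].
#' @return HU-valued matrix `out_size x out_size`.
#' @export
back_project <- function(s, out_size, params = sim_params()) {
  filt <- ramp_filter_rows(s$values)
  rec <- cpp_backproject(filt, s$angles, out_size, out_size)
  .clamp_hu(rec - params$attenuation_offset)
}

#' Extract the body mask of an HU slice
#'
#' Thresholds at -500 HU and keeps the largest connected component,
#' which separates the body from the couch slab.
#'
#' @param img HU-valued matrix.
#' @return logical matrix.
#' @export
body_mask <- function(img) {
  mask <- img > -500
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  matrix(lab == which.max(tab), nrow(img), ncol(img))
}

#' Sample a truncating isocentre
#'
#' Rejection-samples candidate isocentres uniformly over the body mask
#' until at least `min_outside_fraction` of body pixels lie farther than
#' `fov_radius` from the candidate — i.e. until the simulated acquisition
#' would genuinely truncate the patient. Deterministic per seed.
#'
#' @param mask logical body mask.
#' @param params [sim_params()].
#' @param seed integer seed.
#' @param max_attempts attempt budget before giving up.
#' @return list with `row` and `col` (1-based pixel indices).
#' @export
sample_isocentre <- function(mask, params = sim_params(), seed = 1L,
                             max_attempts = 2000L) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("body mask is empty")
  set.seed(derive_seed(seed, "isocentre"))
  n_body <- nrow(idx)
  r2 <- params$fov_radius^2
  need <- params$min_outside_fraction * n_body
  for (att in seq_len(max_attempts)) {
    k <- sample.int(n_body, 1L)
    cand <- idx[k, ]
    outside <- sum((idx[, 1] - cand[1])^2 + (idx[, 2] - cand[2])^2 > r2)
    if (outside >= need)
      return(list(row = unname(cand[1]), col = unname(cand[2])))
  }
  stop("cannot truncate: no isocentre leaves >= ",
       params$min_outside_fraction * 100,
       "% of the body outside the field of view")
}

#' Apply a circular field-of-view mask
#'
#' Pixels whose centre lies farther than `fov_radius` from the isocentre
#' are assigned stored intensity 0, emulating partial CBCT acquisition.
#' The image is neither recentred nor cropped.
#'
#' @param img matrix.
#' @param iso list with `row`, `col` (1-based).
#' @param params [sim_params()].
#' @return matrix of identical dimensions.
#' @export
apply_fov_mask <- function(img, iso, params = sim_params()) {
  h <- nrow(img); w <- ncol(img)
  if (iso$row < 1 || iso$row > h || iso$col < 1 || iso$col > w)
    stop("isocentre lies outside the image")
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  out <- img
  out[(r - iso$row)^2 + (c - iso$col)^2 > params$fov_radius^2] <- 0
  out
}

#' Simulate a synthetic CBCT slice from a CT slice
#'
#' Full simulation chain: elastic deformation, forward projection of both
#' original and distorted images, partial sinogram replacement, filtered
#' back-projection, isocentre sampling on the body mask, and circular FOV
#' truncation. The streak-free ground truth is the original CT under the
#' same FOV mask; the full-anatomy ground truth is the original CT.
#'
#' @param ct HU-valued CT slice (matrix).
#' @param params [sim_params()].
#' @param seed integer seed; the whole pair is reproducible from it.
#' @return object of class `sim_pair`: list with `scbct`, `streak_gt`,
#'   `full_gt`, `isocentre`, `seed`, `replaced_fraction`.
#' @export
simulate_scbct_slice <- function(ct, params = sim_params(), seed = 1L) {
  distorted <- elastic_deform(ct, params, seed = seed)
  s_orig <- forward_project(ct, params)
  s_dist <- forward_project(distorted, params)
  mixed <- mix_sinograms(s_orig, s_dist, params, seed = seed)
  recon <- back_project(mixed$sinogram, nrow(ct), params)
  iso <- sample_isocentre(body_mask(ct), params, seed = seed)
  structure(
    list(scbct = apply_fov_mask(recon, iso, params),
         streak_gt = apply_fov_mask(ct, iso, params),
         full_gt = ct,
         isocentre = iso, seed = seed,
         replaced_fraction = mixed$replaced_fraction),
    class = "sim_pair"
  )
}

#' @export
print.sim_pair <- function(x, ...) {
  cat(sprintf(paste0("<sim_pair> %dx%d px, isocentre (%d, %d), ",
                     "replaced fraction %.4f, seed %d\n"),
              nrow(x$scbct), ncol(x$scbct), x$isocentre$row, x$isocentre$col,
              x$replaced_fraction, x$seed))
  invisible(x)
}

#' Simulate a setup-CBCT volume from a CT volume
#'
#' Applies [simulate_scbct_slice()] to every slice with per-slice derived
#' seeds. Returns both the simulated CBCT volume (model input) and the
#' per-slice `sim_pair` objects (carrying ground truths and provenance).
#'
#' @param ct_vol a [ct_volume()].
#' @param params [sim_params()].
#' @param seed integer seed.
#' @return list with `cbct` (a `ct_volume`) and `pairs` (list of
#'   `sim_pair`).
#' @export
simulate_scbct_volume <- function(ct_vol, params = sim_params(), seed = 1L) {
  pairs <- lapply(seq_along(ct_vol$slices), function(i) {
    simulate_scbct_slice(ct_vol$slices[[i]], params,
                         seed = derive_seed(seed, "simulate", i))
  })
  cbct <- ct_volume(lapply(pairs, `[[`, "scbct"),
                    slice_thickness = ct_vol$slice_thickness,
                    patient_id = paste0(ct_vol$patient_id, "-scbct"))
  list(cbct = cbct, pairs = pairs)
}
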