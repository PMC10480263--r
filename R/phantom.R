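#' Specification of a synthetic thorax phantom slice
#'
#' Describes an axial thorax slice as a set of analytic structures: an
#' outer body ellipse with a fat rim, two lung ellipses, bone sites
#' (spine, sternum, ribs) and a full-width treatment-couch slab. All
#' geometry defaults scale proportionally with `image_size`, so the same
#' anatomy renders at the clinical 512 px grid or at a reduced desk-scale
#' grid. Structures are rasterised exactly (hard level sets), which makes
#' analytic masks usable as test oracles.
#'
#' @param image_size pixels per side (square grid); default 512.
#' @param body_centre,body_axes centre (row, col) and semi-axes (row, col)
#'   of the outer body ellipse, px.
#' @param lungs list of two `list(centre =, axes =)` ellipse definitions.
#' @param bone_sites list of `list(centre =, axes =)` ellipse definitions
#'   for spine, sternum and ribs.
#' @param couch_row row index (1-based) of the couch top surface; must lie
#'   below the lowest extent of the body ellipse.
#' @param couch_thickness couch slab thickness in px.
#' @param hu_values named list of HU levels for air, lung, soft_tissue,
#'   fat, bone and couch; all must lie in `[-1024, 3071]`.
#' @param jitter fractional per-structure size/position perturbation scale
#'   used by [make_cohort()] to vary anatomy between patients; a smaller
#'   per-slice drift (jitter / 5 per step) varies anatomy within a patient.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512,
                         body_centre = NULL, body_axes = NULL,
                         lungs = NULL, bone_sites = NULL,
                         couch_row = NULL, couch_thickness = NULL,
                         hu_values = list(air = -1000, lung = -750,
                                          soft_tissue = 40, fat = -90,
                                          bone = 700, couch = 100),
                         jitter = 0.05) {
  s <- image_size
  if (is.null(body_centre)) body_centre <- c(0.50, 0.50) * s
  if (is.null(body_axes))   body_axes   <- c(0.28, 0.40) * s
  if (is.null(lungs)) {
    lungs <- list(
      left  = list(centre = c(0.48, 0.33) * s, axes = c(0.17, 0.13) * s),
      right = list(centre = c(0.48, 0.67) * s, axes = c(0.17, 0.13) * s)
    )
  }
  if (is.null(bone_sites)) {
    rib_angles <- seq(-150, 150, length.out = 8) * pi / 180
    ribs <- lapply(seq_along(rib_angles), function(i) {
      a <- rib_angles[i]
      list(centre = body_centre + 0.88 * body_axes * c(cos(a), sin(a)),
           axes = c(0.013, 0.013) * s)
    })
    names(ribs) <- paste0("rib", seq_along(ribs))
    bone_sites <- c(
      list(spine   = list(centre = c(0.70, 0.50) * s, axes = c(0.045, 0.045) * s),
           sternum = list(centre = c(0.245, 0.50) * s, axes = c(0.020, 0.045) * s)),
      ribs
    )
  }
  if (is.null(couch_row)) couch_row <- round(0.85 * s)
  if (is.null(couch_thickness)) couch_thickness <- max(3L, round(10 * s / 512))
  spec <- structure(
    list(image_size = as.integer(s), body_centre = body_centre,
         body_axes = body_axes, lungs = lungs, bone_sites = bone_sites,
         couch_row = as.integer(couch_row),
         couch_thickness = as.integer(couch_thickness),
         hu_values = hu_values, jitter = jitter),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

ellipse_inside_image <- function(centre, axes, s) {
  centre[1] - axes[1] >= 1 && centre[1] + axes[1] <= s &&
    centre[2] - axes[2] >= 1 && centre[2] + axes[2] <= s
}

ellipse_inside_ellipse <- function(centre, axes, c2, a2) {
  th <- seq(0, 2 * pi, length.out = 64)
  pr <- centre[1] + axes[1] * cos(th)
  pc <- centre[2] + axes[2] * sin(th)
  all(((pr - c2[1]) / a2[1])^2 + ((pc - c2[2]) / a2[2])^2 <= 1)
}

validate_phantom_spec <- function(spec) {
  s <- spec$image_size
  if (!ellipse_inside_image(spec$body_centre, spec$body_axes, s))
    stop("phantom structure 'body' extends outside the image")
  for (nm in names(spec$lungs)) {
    l <- spec$lungs[[nm]]
    if (!ellipse_inside_ellipse(l$centre, l$axes, spec$body_centre, spec$body_axes))
      stop(sprintf("phantom structure 'lung:%s' is not inside the body", nm))
  }
  for (nm in names(spec$bone_sites)) {
    b <- spec$bone_sites[[nm]]
    if (!ellipse_inside_image(b$centre, b$axes, s))
      stop(sprintf("phantom structure 'bone:%s' extends outside the image", nm))
  }
  body_low <- spec$body_centre[1] + spec$body_axes[1]
  if (spec$couch_row <= body_low)
    stop("phantom structure 'couch': couch_row must lie below the body ellipse")
  if (spec$couch_row + spec$couch_thickness - 1 > s)
    stop("phantom structure 'couch' extends outside the image")
  hv <- unlist(spec$hu_values)
  if (any(hv < hu_min | hv > hu_max))
    stop("phantom 'hu_values' must lie in [-1024, 3071]")
  invisible(spec)
}

ellipse_mask <- function(s, centre, axes) {
  r <- matrix(seq_len(s), s, s)
  c <- matrix(seq_len(s), s, s, byrow = TRUE)
  ((r - centre[1]) / axes[1])^2 + ((c - centre[2]) / axes[2])^2 <= 1
}

#' Render a thorax phantom slice
#'
#' Rasterises a [phantom_spec()] into an HU-valued slice: air background,
#' couch slab, fat body rim, soft-tissue interior, lungs and bone sites,
#' painted in that order so later structures overwrite earlier ones.
#' Rendering is exact and deterministic for a fixed `(spec, seed)`; the
#' seed is reserved for stochastic rendering options and does not affect
#' the default hard-edged rasterisation.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed (kept for interface symmetry with the seeded
#'   cohort generator).
#' @return numeric matrix (`image_size` x `image_size`) in HU.
#' @export
make_thorax_phantom <- function(spec = phantom_spec(), seed = 1L) {
  validate_phantom_spec(spec)
  s <- spec$image_size
  hv <- spec$hu_values
  img <- matrix(hv$air, s, s)
  couch_rows <- spec$couch_row:min(s, spec$couch_row + spec$couch_thickness - 1L)
  img[couch_rows, ] <- hv$couch
  body <- ellipse_mask(s, spec$body_centre, spec$body_axes)
  img[body] <- hv$fat
  inner <- ellipse_mask(s, spec$body_centre, 0.93 * spec$body_axes)
  img[inner] <- hv$soft_tissue
  for (l in spec$lungs)
    img[ellipse_mask(s, l$centre, l$axes)] <- hv$lung
  for (b in spec$bone_sites)
    img[ellipse_mask(s, b$centre, b$axes)] <- hv$bone
  img
}

jitter_spec <- function(spec, factors) {
  # factors: multiplicative size factors plus additive positional offsets
  # (fractions of the relevant size parameter). Interior structures move
  # and scale with the body so containment survives jittering.
  sp <- spec
  sp$body_axes <- spec$body_axes * factors$body_size
  sp$body_centre <- spec$body_centre + factors$body_shift * spec$body_axes
  relocate <- function(centre) {
    rel <- centre - spec$body_centre
    sp$body_centre + rel * factors$body_size
  }
  for (i in seq_along(sp$lungs)) {
    sp$lungs[[i]]$axes <- spec$lungs[[i]]$axes * factors$lung_size[i]
    sp$lungs[[i]]$centre <- relocate(spec$lungs[[i]]$centre) +
      factors$lung_shift[[i]] * spec$lungs[[i]]$axes
  }
  for (i in seq_along(sp$bone_sites)) {
    sp$bone_sites[[i]]$axes <- spec$bone_sites[[i]]$axes * factors$bone_size[i]
    sp$bone_sites[[i]]$centre <- relocate(spec$bone_sites[[i]]$centre) +
      factors$bone_shift[[i]] * pmax(spec$bone_sites[[i]]$axes, 2)
  }
  sp
}

clamp_factors <- function(f, jitter) {
  cl <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  list(
    body_size = cl(f$body_size, 1 - jitter, 1 + jitter),
    body_shift = cl(f$body_shift, -jitter, jitter),
    lung_size = cl(f$lung_size, 1 - jitter, 1 + jitter),
    lung_shift = lapply(f$lung_shift, cl, -jitter, jitter),
    bone_size = cl(f$bone_size, 1 - jitter, 1 + jitter),
    bone_shift = lapply(f$bone_shift, cl, -jitter, jitter)
  )
}

draw_jitter_factors <- function(spec, scale) {
  u <- function(n = 1) runif(n, -scale, scale)
  list(
    body_size = 1 + u(), body_shift = u(2),
    lung_size = 1 + u(length(spec$lungs)),
    lung_shift = lapply(seq_along(spec$lungs), function(i) u(2)),
    bone_size = 1 + u(length(spec$bone_sites)),
    bone_shift = lapply(seq_along(spec$bone_sites), function(i) u(2))
  )
}

add_factors <- function(f, g) {
  # combine two factor draws: sizes multiply, shifts add
  list(
    body_size = f$body_size * g$body_size,
    body_shift = f$body_shift + g$body_shift,
    lung_size = f$lung_size * g$lung_size,
    lung_shift = Map(`+`, f$lung_shift, g$lung_shift),
    bone_size = f$bone_size * g$bone_size,
    bone_shift = Map(`+`, f$bone_shift, g$bone_shift)
  )
}

#' Generate a cohort of phantom CT volumes
#'
#' Draws one set of per-structure jitter factors per patient (uniform on
#' `[-jitter, +jitter]` as a fraction of each size/position parameter),
#' then applies a smaller per-slice random drift (steps of `jitter / 5`)
#' so anatomy varies smoothly through each volume. Patient identifiers
#' are unique and generation is fully determined by `seed`.
#'
#' @param n_patients,slices_per_patient counts, both at least 1.
#' @param spec base [phantom_spec()].
#' @param seed integer seed.
#' @param slice_thickness mm, stored on each volume.
#' @return list of [ct_volume()] objects.
#' @export
make_cohort <- function(n_patients, slices_per_patient, spec = phantom_spec(),
                        seed = 1L, slice_thickness = 3) {
  if (n_patients < 1 || slices_per_patient < 1)
    stop("counts must be >= 1")
  validate_phantom_spec(spec)
  lapply(seq_len(n_patients), function(p) {
    set.seed(derive_seed(seed, "phantom", p))
    patient_factors <- draw_jitter_factors(spec, spec$jitter)
    drift <- draw_jitter_factors(spec, 0)  # identity
    slices <- vector("list", slices_per_patient)
    for (k in seq_len(slices_per_patient)) {
      if (k > 1) {
        step <- draw_jitter_factors(spec, spec$jitter / 5)
        drift <- clamp_factors(add_factors(drift, step), spec$jitter)
      }
      sp <- jitter_spec(spec, add_factors(patient_factors, drift))
      slices[[k]] <- make_thorax_phantom(sp, seed = seed)
    }
    ct_volume(slices, slice_thickness = slice_thickness,
              patient_id = sprintf("P%03d", p))
  })
}
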