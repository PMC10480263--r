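#' Construct a CT volume
#'
#' A `ct_volume` is an ordered stack of equally sized axial slices in
#' Hounsfield units, with a common slice thickness and an opaque patient
#' label. It is the container passed between the phantom generator, the
#' simulator, preprocessing and the model.
#'
#' @param slices list of numeric matrices, all with identical dimensions.
#' @param slice_thickness slice spacing in mm; must be positive.
#' @param patient_id opaque character label.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(slices, slice_thickness = 1, patient_id = "anon") {
  if (!is.list(slices) || length(slices) == 0L)
    stop("'slices' must be a nonempty list of matrices")
  dims <- vapply(slices, dim, integer(2))
  if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1]))
    stop("all slices must share dimensions")
  if (!is.numeric(slice_thickness) || slice_thickness <= 0)
    stop("'slice_thickness' must be positive")
  structure(
    list(slices = slices, slice_thickness = as.numeric(slice_thickness),
         patient_id = as.character(patient_id)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<ct_volume> patient %s: %d slice(s) of %dx%d px, thickness %g mm\n",
              x$patient_id, length(x$slices), d[1], d[2], x$slice_thickness))
  rng <- range(unlist(lapply(x$slices, range)))
  cat(sprintf("  intensity range [%.1f, %.1f] HU\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
length.ct_volume <- function(x) length(x$slices)

#' Volume shape accessors
#'
#' @param vol a [ct_volume()].
#' @return `n_slices()`: the slice count; `slice_dim()`: the in-plane
#'   dimensions.
#' @export
n_slices <- function(vol) length(vol$slices)

#' @rdname n_slices
#' @export
slice_dim <- function(vol) dim(vol$slices[[1]])
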