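#' Read a CT/CBCT volume from disk
#'
#' NIfTI volumes are read with intensities taken as already
#' HU-calibrated (scale slope/intercept applied by the reader) and slice
#' thickness extracted from the z pixel dimension. DICOM series are not
#' supported by this build and raise an informative error.
#'
#' @param path file path.
#' @param format `"nifti"` or `"dicom"`.
#' @param patient_id label to attach; defaults to the file stem.
#' @return a [ct_volume()].
#' @export
read_volume <- function(path, format = c("nifti", "dicom"),
                        patient_id = NULL) {
  format <- match.arg(format)
  if (format == "dicom")
    stop("DICOM series are not supported by this build; convert to NIfTI")
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  pd <- RNifti::pixdim(img)
  thick <- if (length(pd) >= 3 && pd[3] > 0) pd[3] else 1
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  ct_volume(lapply(seq_len(dim(arr)[3]), function(i) arr[, , i]),
            slice_thickness = thick, patient_id = patient_id)
}

#' Write a CT/CBCT volume to disk
#'
#' NIfTI output stores double-precision intensities (lossless for HU
#' values) with the slice thickness in the z pixel dimension.
#'
#' @param vol a [ct_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param format `"nifti"` (DICOM is not supported by this build).
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "dicom")
    stop("DICOM series are not supported by this build; use NIfTI")
  d <- slice_dim(vol)
  arr <- array(0, c(d[1], d[2], n_slices(vol)))
  for (i in seq_len(n_slices(vol))) arr[, , i] <- vol$slices[[i]]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, vol$slice_thickness)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
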