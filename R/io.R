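#' Read a NIfTI volume as a plain array with spacing/TR attributes
#'
#' Thin wrapper around [RNifti::readNifti()] that returns a base R array with
#' `spacing` (mm per spatial axis) and, for 4D data, `tr` (seconds) attached
#' as attributes, the form every map computation in this package consumes.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param ndim Expected dimensionality (3 or 4); a mismatch is an error.
#' @return An array with attributes `spacing` and (4D) `tr`.
#' @export
read_nifti <- function(path, ndim = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (!is.null(ndim) && length(dim(arr)) != ndim)
    stop(sprintf("expected %d-dimensional image, got %d dims", ndim,
                 length(dim(arr))), call. = FALSE)
  attr(arr, "spacing") <- pd[seq_len(min(3L, length(pd)))]
  if (length(dim(arr)) == 4L) {
    tr <- pd[4]
    # pixdim[4] in NIfTI carries the repetition time for 4D series
    attr(arr, "tr") <- if (is.finite(tr) && tr > 0) tr else NA_real_
  }
  arr
}

#' Write an array to NIfTI, recording voxel spacing and TR
#'
#' @param arr 3D or 4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm (length 3); defaults to the array's
#'   `spacing` attribute or 1 mm isotropic.
#' @param tr Repetition time in seconds for 4D arrays.
#' @return The path, invisibly.
#' @export
write_nifti <- function(arr, path, spacing = NULL, tr = NULL) {
  if (is.null(spacing)) spacing <- attr(arr, "spacing")
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (is.null(tr)) tr <- attr(arr, "tr")
  pixdim <- spacing[1:3]
  if (length(dim(arr)) == 4L) pixdim <- c(pixdim, if (is.null(tr) || is.na(tr)) 1 else tr)
  img <- RNifti::asNifti(array(as.numeric(arr), dim = dim(arr)))
  RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Get/attach volume metadata
#'
#' Helpers used throughout the pipeline: `vol_spacing()` falls back to
#' 1 mm isotropic, `vol_tr()` errors when the TR is needed but absent.
#' @param arr An array as returned by [read_nifti()] or a phantom generator.
#' @return Numeric spacing (mm) or TR (s).
#' @export
vol_spacing <- function(arr) {
  sp <- attr(arr, "spacing")
  if (is.null(sp)) rep(1, 3) else as.numeric(sp[1:3])
}

#' @rdname vol_spacing
#' @export
vol_tr <- function(arr) {
  tr <- attr(arr, "tr")
  if (is.null(tr) || is.na(tr)) stop("volume has no TR attribute", call. = FALSE)
  as.numeric(tr)
}
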