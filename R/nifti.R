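# Optional NIfTI glue for users with real ROI data.  The synthetic pipeline
# is purely matrix-based; these helpers lay an ROI's voxels out in a flat
# synthetic volume (one slice, voxels on a near-square grid) so timeseries
# can round-trip through standard imaging tools.

#' Write a BOLD timeseries as a 4D NIfTI with an ROI mask
#'
#' Voxels are arranged on a near-square single-slice grid; a companion mask
#' volume marks which grid cells hold data.  Requires the RNifti package.
#'
#' @param Y Timeseries matrix (volumes x voxels) or a `bold_timeseries`.
#' @param path Output path for the 4D series (`.nii` / `.nii.gz`).
#' @param mask_path Output path for the 3D mask; default derived from `path`.
#' @param tr Repetition time in seconds, stored in the header.
#' @return Invisibly, a list with the grid dimensions and the mask path.
#' @export
write_bold_nifti <- function(Y, path, mask_path = NULL, tr = 2) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI output")
  }
  if (inherits(Y, "bold_timeseries")) { tr <- Y$tr; Y <- Y$Y }
  Y <- as.matrix(Y)
  n_vols <- nrow(Y); n_vox <- ncol(Y)
  nx <- ceiling(sqrt(n_vox)); ny <- ceiling(n_vox / nx)
  vol <- array(0, c(nx, ny, 1L, n_vols))
  mask <- array(0L, c(nx, ny, 1L))
  mask[seq_len(n_vox)] <- 1L
  for (v in seq_len(n_vols)) {
    plane <- array(0, c(nx, ny, 1L))
    plane[seq_len(n_vox)] <- Y[v, ]
    vol[, , , v] <- plane
  }
  if (is.null(mask_path)) {
    mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  }
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(1, 1, 1, tr)
  RNifti::writeNifti(img, path)
  RNifti::writeNifti(RNifti::asNifti(mask), mask_path)
  invisible(list(dim = c(nx, ny, 1L), mask_path = mask_path))
}

#' Read an ROI timeseries from a 4D NIfTI plus mask
#'
#' @param path 4D NIfTI timeseries.
#' @param mask_path 3D mask; nonzero cells define the ROI.  `NULL` takes every
#'   nonzero-variance voxel.
#' @return Timeseries matrix, volumes x voxels (mask order).
#' @export
read_roi_timeseries <- function(path, mask_path = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI input")
  }
  img <- as.array(RNifti::readNifti(path))
  if (length(dim(img)) != 4L) stop("expected a 4D timeseries image")
  n_vols <- dim(img)[4L]
  flat <- matrix(img, ncol = n_vols)  # voxels x volumes
  if (!is.null(mask_path)) {
    mask <- as.array(RNifti::readNifti(mask_path))
    keep <- which(mask != 0)
  } else {
    keep <- which(apply(flat, 1L, function(x) any(x != x[1L])))
  }
  t(flat[keep, , drop = FALSE])
}
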