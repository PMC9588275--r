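#' CT image volume
#'
#' A minimal container for a 3-D CT scan in Hounsfield units (HU): a voxel
#' array, the physical voxel spacing in millimetres and a subject identifier.
#' Slices are the third array dimension and are processed independently by
#' the simulation and denoising code (2-D slice-based networks).
#'
#' @param voxels numeric 3-D array of HU values (x, y, slice). A matrix is
#'   promoted to a single-slice volume.
#' @param spacing numeric length-3 vector, voxel spacing in mm (x, y, z);
#'   all components must be positive.
#' @param subject_id character scalar identifying the scan.
#'
#' @return An object of class `ct_volume`: a list with elements `voxels`,
#'   `spacing` and `subject_id`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), subject_id = "subject") {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stopf("`voxels` must be a 3-D array (or a matrix for a single slice)")
  }
  if (!all(is.finite(voxels))) stopf("HU values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stopf("`spacing` must be three positive numbers (mm)")
  }
  structure(
    list(voxels = voxels, spacing = spacing,
         subject_id = as.character(subject_id)[1]),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %s: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU [%.0f, %.0f]\n",
              x$subject_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

n_slices <- function(volume) dim(volume$voxels)[3]

get_slice <- function(volume, i) volume$voxels[, , i]

#' Read / write CT volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} that carry the voxel spacing in the
#' NIfTI header and the subject id in the file name.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param volume a [ct_volume()].
#' @return `read_volume()` returns a `ct_volume`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)
  vox <- as.array(img)
  if (length(dim(vox)) == 2L) vox <- array(vox, dim = c(dim(vox), 1L))
  ct_volume(vox, spacing = spacing[seq_len(3)],
            subject_id = sub("\\.nii(\\.gz)?$", "", basename(path)))
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels, pixdim = volume$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
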