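# NIfTI and text-format I/O: thin wrappers over RNifti plus FSL-style
# .bval/.bvec and YAML ROI tables.

#' Write a diffusion volume to NIfTI + bval/bvec
#'
#' Writes the 4D signal as compressed NIfTI and the gradient scheme as
#' FSL-style text sidecars: `<prefix>.nii.gz`, `<prefix>.bval` (one line of
#' b-values) and `<prefix>.bvec` (three lines: x, y, z components).
#'
#' @param dwi A [diffusion_volume()].
#' @param prefix Output path without extension.
#' @return Invisibly, the NIfTI path.
#' @export
write_dwi_nifti <- function(dwi, prefix) {
  assert_that(inherits(dwi, "diffusion_volume"), "`dwi` must be a diffusion_volume")
  img <- RNifti::asNifti(dwi$signal)
  RNifti::pixdim(img) <- dwi$voxel_size
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  writeLines(paste(format(dwi$bvalues, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  writeLines(apply(dwi$bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")),
    paste0(prefix, ".bvec"))
  invisible(nii)
}

#' Read a diffusion volume from NIfTI + bval/bvec
#'
#' @param nii Path to the 4D NIfTI file.
#' @param bval,bvec Paths to the FSL-style sidecars; default to `nii` with
#'   the extensions swapped.
#' @return A [diffusion_volume()].
#' @export
read_dwi_nifti <- function(nii, bval = NULL, bvec = NULL) {
  stem <- sub("\\.nii(\\.gz)?$", "", nii)
  bval <- bval %||% paste0(stem, ".bval")
  bvec <- bvec %||% paste0(stem, ".bvec")
  img <- RNifti::readNifti(nii)
  bvalues <- scan(bval, quiet = TRUE)
  bvecs <- matrix(scan(bvec, quiet = TRUE), nrow = 3, byrow = TRUE)
  diffusion_volume(array(as.numeric(img), dim = dim(img)), bvalues, bvecs,
                   voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write a 3D volume as NIfTI
#'
#' @param vol 3D array (numeric or logical; logical is stored as 0/1).
#' @param path Output `.nii.gz` path.
#' @param voxel_size mm per axis.
#' @return Invisibly, `path`.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D volume from NIfTI
#'
#' @param path NIfTI path.
#' @return List with `data` (3D array) and `voxel_size`.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxel_size = RNifti::pixdim(img)[1:3])
}

#' Read an ROI table from YAML
#'
#' The YAML file holds a list of ROIs, each with `fiber_type`
#' ("projection"/"association"), `hemisphere`, `center` (x, y, z in world mm,
#' RAS) and optional `diameter` (mm, default 5).
#'
#' @param path YAML file path.
#' @return Tibble with columns `fiber_type`, `hemisphere`, `x`, `y`, `z`,
#'   `diameter`.
#' @export
read_roi_table <- function(path) {
  rois <- yaml::read_yaml(path)
  assert_that(length(rois) >= 1, "ROI file is empty")
  purrr::map_dfr(rois, function(r) {
    assert_that(!is.null(r$fiber_type) && !is.null(r$center),
                "each ROI needs `fiber_type` and `center`")
    tibble::tibble(
      fiber_type = r$fiber_type,
      hemisphere = r$hemisphere %||% "left",
      x = r$center[[1]], y = r$center[[2]], z = r$center[[3]],
      diameter = r$diameter %||% 5
    )
  })
}

#' Write an ROI table to YAML
#'
#' @param roi_table Tibble as returned by [read_roi_table()] or
#'   [phantom_roi_table()].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_roi_table <- function(roi_table, path) {
  rois <- purrr::pmap(roi_table, function(fiber_type, hemisphere, x, y, z,
                                          diameter, ...) {
    list(fiber_type = fiber_type, hemisphere = hemisphere,
         center = c(x, y, z), diameter = diameter)
  })
  yaml::write_yaml(rois, path)
  invisible(path)
}
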