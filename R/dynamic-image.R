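#' Dynamic PET image container
#'
#' A 4D dynamic image: a numeric array `(x, y, z, frame)` of activity
#' concentrations (kBq/mL) together with its frame schedule and voxel size.
#'
#' @param data 4D numeric array; 4th dimension indexes frames.
#' @param schedule A `frame_schedule` whose length matches `dim(data)[4]`.
#' @param voxel_size_mm Voxel edge lengths, length 3 (default 3.125 mm
#'   isotropic in-plane with 2.89 mm slices, as on total-body scanners).
#' @return A `dynamic_image` object.
#' @export
dynamic_image <- function(data, schedule, voxel_size_mm = c(3.125, 3.125, 2.89)) {
  if (length(dim(data)) != 4) stop("`data` must be a 4D array")
  validate_schedule(schedule)
  if (dim(data)[4] != nrow(schedule)) {
    stop("frame axis length must equal the schedule length")
  }
  if (any(!is.finite(data))) stop("image values must be finite")
  structure(list(data = data, schedule = schedule,
                 voxel_size_mm = voxel_size_mm),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dynamic_image: %d x %d x %d voxels, %d frames, %.1f-min span\n",
              d[1], d[2], d[3], d[4], max(x$schedule$end)))
  invisible(x)
}

#' Extract the mean TAC over an ROI mask
#'
#' Averages the activity of all voxels inside the mask, frame by frame --
#' the standard ROI TAC, also used for image-derived input functions from a
#' blood-pool (e.g. ascending aorta) mask.
#'
#' @param image A `dynamic_image`.
#' @param mask Logical (or 0/1) 3D array on the same spatial grid.
#' @return A `pet_tac`.
#' @export
extract_roi_tac <- function(image, mask) {
  stopifnot(inherits(image, "dynamic_image"))
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(mask), dim(image$data)[1:3])) {
    stop("mask must match the image spatial grid")
  }
  if (!any(mask)) stop("mask is empty")
  nframe <- dim(image$data)[4]
  flat <- matrix(image$data, ncol = nframe)
  vals <- colMeans(flat[as.vector(mask), , drop = FALSE])
  tac(image$schedule, vals)
}

#' Write parametric maps as NIfTI volumes
#'
#' One 3D NIfTI file per parameter. Requires the RNifti package.
#'
#' @param maps A `parametric_maps` object (see [fit_parametric_images()]).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the written file paths.
#' @export
write_parametric_nifti <- function(maps, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required to write NIfTI volumes")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(maps$maps), function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(maps$maps[[nm]],
                                       pixdim = maps$voxel_size_mm), p)
    p
  }, character(1))
  invisible(paths)
}
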