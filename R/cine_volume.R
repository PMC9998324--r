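#' Cine label volume
#'
#' Container for a 4D short-axis cine segmentation: an integer label array
#' indexed `[row, col, slice, phase]` with values 0 (background), 1 (left
#' ventricle) and 2 (right ventricle), together with the physical voxel
#' spacing. Slice 1 is the most apical slice and the last slice the most
#' basal, mirroring the usual short-axis stack ordering from apex to base.
#'
#' @param labels 4D integer array `[row, col, slice, phase]` with values
#'   in `{0, 1, 2}`.
#' @param in_plane_spacing_mm numeric length-2 vector, row/column voxel
#'   spacing in millimetres.
#' @param slice_thickness_mm slice thickness in millimetres.
#' @return An object of class `cine_label_volume`.
#' @examples
#' arr <- array(0L, dim = c(8, 8, 3, 4))
#' arr[3:6, 3:6, 2, ] <- 1L
#' vol <- cine_label_volume(arr, c(1.25, 1.25), 8)
#' n_phases(vol)
#' @export
cine_label_volume <- function(labels, in_plane_spacing_mm = c(1.25, 1.25),
                              slice_thickness_mm = 8) {
  if (!is.array(labels) || length(dim(labels)) != 4L) {
    abort("`labels` must be a 4D array [row, col, slice, phase].")
  }
  if (!all(labels %in% c(0L, 1L, 2L))) {
    abort("label values must be 0 (background), 1 (LV) or 2 (RV).")
  }
  in_plane_spacing_mm <- rep(as.numeric(in_plane_spacing_mm), length.out = 2L)
  if (any(in_plane_spacing_mm <= 0) || slice_thickness_mm <= 0) {
    abort("voxel spacings must be positive.")
  }
  if (dim(labels)[4] < 2L) {
    abort("a cine volume needs at least 2 cardiac phases.")
  }
  storage.mode(labels) <- "integer"
  structure(
    list(
      labels = labels,
      in_plane_spacing_mm = in_plane_spacing_mm,
      slice_thickness_mm = as.numeric(slice_thickness_mm)
    ),
    class = "cine_label_volume"
  )
}

#' @export
print.cine_label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<cine_label_volume> %d x %d in-plane, %d slices, %d phases\n",
    d[1], d[2], d[3], d[4]
  ))
  cat(sprintf(
    "  spacing: %.2f x %.2f mm in-plane, %.1f mm slices\n",
    x$in_plane_spacing_mm[1], x$in_plane_spacing_mm[2], x$slice_thickness_mm
  ))
  vox <- voxel_volume_ml(x)
  for (s in c("LV", "RV")) {
    n <- sum(x$labels[, , , 1] == structure_label(s))
    cat(sprintf("  %s at phase 1: %.1f ml\n", s, n * vox))
  }
  invisible(x)
}

#' @rdname cine_label_volume
#' @param vol a `cine_label_volume`.
#' @export
n_phases <- function(vol) dim(vol$labels)[4]

#' @rdname cine_label_volume
#' @export
n_slices <- function(vol) dim(vol$labels)[3]

#' Physical volume of one voxel, in millilitres
#' @param vol a `cine_label_volume`.
#' @keywords internal
voxel_volume_ml <- function(vol) {
  prod(vol$in_plane_spacing_mm) * vol$slice_thickness_mm / 1000
}

#' Extract the 3D label grid at one cardiac phase
#'
#' @param vol a `cine_label_volume`.
#' @param phase phase index (1-based).
#' @return 3D integer array `[row, col, slice]`.
#' @export
phase_labels <- function(vol, phase) {
  stopifnot(phase >= 1, phase <= n_phases(vol))
  vol$labels[, , , phase, drop = TRUE]
}

# slice indices (apex..base) containing any voxel of `label` in a 3D grid;
# integer(0) when absent
occupied_slices <- function(grid3d, label) {
  which(apply(grid3d == label, 3, any))
}

#' Read and write cine label volumes as 4D NIfTI
#'
#' The label array is stored as a 4D NIfTI image with the voxel spacing in
#' the header (`pixdim`); the 4th dimension indexes cardiac phase.
#'
#' @param vol a `cine_label_volume`.
#' @param path file path, conventionally ending in `.nii.gz`.
#' @return `write_cine_nifti()` returns `path` invisibly;
#'   `read_cine_nifti()` returns a `cine_label_volume`.
#' @export
write_cine_nifti <- function(vol, path) {
  arr <- vol$labels
  attr(arr, "pixdim") <- c(vol$in_plane_spacing_mm, vol$slice_thickness_mm, 1)
  img <- RNifti::asNifti(arr, datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_cine_nifti
#' @export
read_cine_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- array(as.integer(img), dim = dim(img))
  cine_label_volume(arr, in_plane_spacing_mm = pd[1:2],
                    slice_thickness_mm = pd[3])
}
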