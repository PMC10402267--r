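#' CT volume container
#'
#' A 3D grid of CT numbers (HU) with voxel spacing and a world-space origin.
#' Axes are ordered (x = left-right, y = anterior-posterior, z =
#' superior-inferior); the world position of the center of 0-based voxel
#' index `i` along an axis is `origin + (i + 0.5) * spacing`, i.e. `origin`
#' is the grid's minimal outer corner. When `origin` is omitted the grid is
#' centered on the world origin.
#'
#' @param data numeric 3D array of CT numbers in HU.
#' @param spacing numeric length-3, voxel spacing in mm per axis.
#' @param origin numeric length-3, world position (mm) of the grid's minimal
#'   outer corner; default centers the volume at (0, 0, 0).
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = NULL) {
  data <- unclass(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  if (is.null(origin)) origin <- -dim(data) * spacing / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]; origin (%.1f, %.1f, %.1f) mm\n",
              min(x$data), max(x$data),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

as_ct_volume <- function(x, template) {
  if (inherits(x, "ct_volume")) return(x)
  ct_volume(x, template$spacing, template$origin)
}

#' World coordinates of voxel centers
#'
#' @param vol a [ct_volume()].
#' @param axis axis index 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of voxel-center world coordinates (mm).
#' @export
voxel_centers <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$spacing[axis]
}

#' Read / write CT volumes as NIfTI
#'
#' Thin wrappers over RNifti that carry the voxel spacing in the NIfTI
#' `pixdim` header. Masks round-trip as integer labels.
#'
#' @param vol a [ct_volume()] (or a logical/integer array for masks).
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `write_nifti_volume` returns `path` invisibly;
#'   `read_nifti_volume` returns a [ct_volume()].
#' @export
write_nifti_volume <- function(vol, path) {
  if (inherits(vol, "ct_volume")) {
    arr <- vol$data
    sp <- vol$spacing
  } else {
    arr <- vol
    sp <- c(1, 1, 1)
    storage.mode(arr) <- "integer"
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  ct_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp)
}

#' 4D CT container
#'
#' An ordered set of respiratory-phase CT volumes sharing one grid, plus the
#' per-phase target (tumor) ROI masks used for region-restricted evaluation.
#'
#' @param phases list of [ct_volume()] on a common grid (phase index 0 is
#'   element 1).
#' @param roi_target list of logical arrays, one per phase, marking target
#'   voxels; each must be non-empty.
#' @return an object of class `ct4d`.
#' @export
ct4d <- function(phases, roi_target) {
  if (!length(phases)) stop("`phases` must be non-empty")
  d <- dim(phases[[1]]$data)
  sp <- phases[[1]]$spacing
  for (p in phases) {
    if (!inherits(p, "ct_volume")) stop("all phases must be ct_volume")
    if (!identical(dim(p$data), d)) stop("all phases must share a grid shape")
    if (!isTRUE(all.equal(p$spacing, sp))) stop("phases must share spacing")
  }
  if (length(roi_target) != length(phases))
    stop("one ROI mask per phase is required")
  for (m in roi_target) {
    if (!identical(dim(m), d)) stop("ROI masks must match the grid")
    if (!any(m)) stop("ROI mask is empty in at least one phase")
  }
  structure(list(phases = phases, roi_target = roi_target,
                 spacing = sp, n_phases = length(phases)),
            class = "ct4d")
}

#' @export
print.ct4d <- function(x, ...) {
  d <- dim(x$phases[[1]]$data)
  cat(sprintf("<ct4d> %d phases, grid %d x %d x %d @ %.3g x %.3g x %.3g mm\n",
              x$n_phases, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Write a 4D CT as per-phase NIfTI files
#'
#' @param x a [ct4d()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the vector of written phase file paths.
#' @export
write_ct4d <- function(x, dir, prefix = "phase") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(x$n_phases)
  for (k in seq_len(x$n_phases)) {
    paths[k] <- file.path(dir, sprintf("%s_%02d.nii.gz", prefix, k - 1))
    write_nifti_volume(x$phases[[k]], paths[k])
    write_nifti_volume(array(as.integer(x$roi_target[[k]]), dim(x$phases[[k]]$data)),
                       file.path(dir, sprintf("%s_%02d_roi.nii.gz", prefix, k - 1)))
  }
  invisible(paths)
}
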