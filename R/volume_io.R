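# NIfTI-1 I/O. Volumes and masks are stored with an axis-aligned affine whose
# diagonal carries the voxel spacing and whose translation column carries the
# origin (world-mm centre of the first voxel). Rotated or sheared affines are
# rejected: the specimen imager context gives no rotation semantics, and an
# axis-aligned contract keeps the index<->world mapping exactly testable.

read_nifti_grid <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  values <- as.array(img)
  d <- dim(values)
  attributes(values) <- NULL  # drop RNifti header attributes
  dim(values) <- d
  if (is.null(d) || length(d) != 3L)
    stop(sprintf("'%s': expected a 3-D volume, header declares %s dimension(s)",
                 path, length(d)), call. = FALSE)
  aff <- RNifti::xform(img)
  lin <- aff[1:3, 1:3]
  if (max(abs(lin - diag(diag(lin)))) > 1e-6 * max(abs(diag(lin))))
    stop(sprintf("'%s': affine is rotated or sheared; only axis-aligned grids are supported",
                 path), call. = FALSE)
  spacing <- abs(diag(lin))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop(sprintf("'%s': non-positive voxel spacing in header pixdim", path),
         call. = FALSE)
  list(values = values, spacing = spacing, origin = as.numeric(aff[1:3, 4]))
}

write_nifti_grid <- function(values, spacing, origin, path, datatype = "auto") {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a scalar volume from a NIfTI-1 file
#'
#' Reads a 3-D CT or PET volume together with its physical grid (spacing and
#' origin) from the header affine. Only axis-aligned affines are accepted.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3-D volume.
#' @return A [volume_grid()].
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path) {
  g <- read_nifti_grid(path)
  volume_grid(g$values, spacing = g$spacing, origin = g$origin)
}

#' Write a scalar volume to a NIfTI-1 file
#'
#' The written file round-trips exactly through [read_volume()]: values,
#' size, spacing and origin are all preserved.
#'
#' @param grid A [volume_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  write_nifti_grid(grid$values, grid$spacing, grid$origin, path,
                   datatype = "double")
  invisible(path)
}

#' Read an integer label mask from a NIfTI-1 file
#'
#' As [read_volume()], but the voxel values must be non-negative integers
#' (label 0 = background); files with fractional voxel values are rejected.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [label_mask()].
#' @export
read_mask <- function(path) {
  g <- read_nifti_grid(path)
  if (max(abs(g$values - round(g$values)), 0) > 0)
    stop(sprintf("'%s': mask contains non-integer voxel values", path),
         call. = FALSE)
  storage.mode(g$values) <- "integer"
  label_mask(g$values, spacing = g$spacing, origin = g$origin)
}

#' Write a label mask to a NIfTI-1 file
#'
#' Stored as 32-bit integers; round-trips exactly through [read_mask()].
#'
#' @param mask A [label_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  write_nifti_grid(mask$labels, mask$spacing, mask$origin, path,
                   datatype = "int32")
  invisible(path)
}
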