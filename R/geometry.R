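# Core lattice containers. Both volumes and masks are plain 3-D arrays plus a
# physical grid: `spacing` (mm per voxel, per axis) and `origin` (world-mm
# coordinate of the CENTRE of voxel (1,1,1); indexing is 1-based in R, the
# world mapping is world = origin + (index - 1) * spacing per axis). Grids are
# axis-aligned: no rotation or shear is representable, by design.

#' Construct a scalar volume on a physical grid
#'
#' A `volume_grid` holds a 3-D scalar field (CT attenuation or PET SUV)
#' together with its voxel spacing and world origin. The world coordinate of
#' voxel \eqn{(i,j,k)} (1-based) is \eqn{origin + (i-1, j-1, k-1) \cdot
#' spacing}; grids are axis-aligned with strictly positive spacing.
#'
#' @param values Numeric 3-D array of voxel values; all values must be finite.
#' @param spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin Numeric length-3, world-mm coordinates of the centre of the
#'   first voxel.
#' @return An object of class `volume_grid` with elements `values`, `spacing`,
#'   `origin`.
#' @examples
#' g <- volume_grid(array(0, c(4, 4, 2)), spacing = c(0.1, 0.1, 0.1))
#' grid_size(g)
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_grid_fields(values, spacing, origin)
  if (!is.double(values)) storage.mode(values) <- "double"
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "volume_grid")
}

#' Construct an integer label mask on a physical grid
#'
#' A `label_mask` shares the `volume_grid` geometry but stores non-negative
#' integer labels; label 0 is background.
#'
#' @param labels Integer 3-D array of non-negative labels (0 = background).
#' @param spacing,origin As in [volume_grid()].
#' @return An object of class `label_mask` with elements `labels`, `spacing`,
#'   `origin`.
#' @examples
#' m <- label_mask(array(0L, c(4, 4, 2)))
#' mask_labels(m)
#' @export
label_mask <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_grid_fields(labels, spacing, origin, what = "labels")
  if (!is.integer(labels)) {
    if (max(abs(labels - round(labels)), 0) > 0)
      stop("mask labels must be integer-valued", call. = FALSE)
    storage.mode(labels) <- "integer"
  }
  if (min(labels) < 0L)
    stop("mask labels must be non-negative", call. = FALSE)
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "label_mask")
}

check_grid_fields <- function(values, spacing, origin, what = "values") {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L)
    stop(sprintf("%s must be a 3-D array (got %s dimensions)",
                 what, if (is.null(d)) "no" else length(d)), call. = FALSE)
  if (any(d < 1L)) stop("grid size must be >= 1 on every axis", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 finite positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)", call. = FALSE)
  if (anyNA(values) || (is.double(values) && any(!is.finite(values))))
    stop(sprintf("%s must be finite throughout", what), call. = FALSE)
  invisible(TRUE)
}

grid_values <- function(x) if (inherits(x, "label_mask")) x$labels else x$values

#' Grid dimensions, in voxels
#' @param x A `volume_grid` or `label_mask`.
#' @return Integer length-3 voxel counts (nx, ny, nz).
#' @export
grid_size <- function(x) dim(grid_values(x))

#' World coordinates of voxel centres along one axis
#'
#' @param x A `volume_grid` or `label_mask`.
#' @param axis Axis index (1, 2 or 3).
#' @return Numeric vector of world-mm coordinates of voxel centres.
#' @export
axis_world_coords <- function(x, axis) {
  n <- grid_size(x)[axis]
  x$origin[axis] + (seq_len(n) - 1) * x$spacing[axis]
}

#' Do two grids share the same geometry?
#' @param a,b Grids (`volume_grid` or `label_mask`).
#' @param tol Absolute tolerance in mm for spacing/origin comparison.
#' @return Logical.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(grid_size(a), grid_size(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Labels present in a mask (excluding background)
#' @param mask A `label_mask`.
#' @return Sorted integer vector of non-zero labels.
#' @export
mask_labels <- function(mask) {
  # tabulate keeps memory flat even on full-scale (10^8-voxel) masks,
  # where unique() would build a gigabyte-scale hash table
  m <- max(mask$labels, 0L)
  if (m == 0L) return(integer(0))
  which(tabulate(mask$labels, nbins = m) > 0L)
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- grid_size(x)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing (%s) mm, origin (%s) mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  value range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  d <- grid_size(x)
  lab <- mask_labels(x)
  cat(sprintf("<label_mask> %d x %d x %d voxels, spacing (%s) mm, origin (%s) mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  %d non-background label(s); foreground voxels: %d\n",
              length(lab), sum(x$labels != 0L)))
  invisible(x)
}

# binary view of a mask as a logical array
as_binary <- function(mask) mask$labels != 0L

# rebuild a mask around a logical/integer array, preserving geometry
with_labels <- function(mask, labels) {
  if (is.logical(labels)) labels <- array(as.integer(labels), dim(labels))
  label_mask(labels, spacing = mask$spacing, origin = mask$origin)
}
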