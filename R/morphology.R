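# Binary 3-D morphology on the node mask. All operators work on logical
# arrays internally; everything outside the volume border is treated as
# background, which makes erosion/dilation exact duals under complementation
# with background padding.
#
# Erosion and dilation are computed by shift-and-accumulate: for each
# structuring-element offset the mask is shifted and summed into an integer
# accumulator; dilation keeps voxels reached at least once, erosion keeps
# voxels covered by every offset. For the small elements used here (ball
# radius 1-3) this is a handful of vectorized passes over the volume.

#' Structuring element for binary morphology
#'
#' @param shape `"ball"` (offsets with Euclidean norm <= radius; radius 1
#'   gives the 6-neighbourhood) or `"cube"` (Chebyshev norm <= radius;
#'   radius 1 gives the 26-neighbourhood).
#' @param radius Radius in voxels (>= 1).
#' @return A list of class `struct_element` with an `offsets` matrix
#'   (including the zero offset), symmetric about the centre.
#' @export
struct_element <- function(shape = c("ball", "cube"), radius = 1L) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  stopifnot(radius >= 1L)
  r <- -radius:radius
  g <- as.matrix(expand.grid(dx = r, dy = r, dz = r))
  keep <- if (shape == "ball") rowSums(g^2) <= radius^2 else rep(TRUE, nrow(g))
  structure(list(shape = shape, radius = radius,
                 offsets = unname(g[keep, , drop = FALSE])),
            class = "struct_element")
}

# neighbour offsets (excluding centre) for a 3-D connectivity
conn_offsets_3d <- function(connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("3-D connectivity must be 6, 18 or 26", call. = FALSE)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nrm <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nrm == 1, "18" = nrm >= 1 & nrm <= 2, "26" = nrm >= 1)
  unname(g[keep, , drop = FALSE])
}

# in-plane neighbour offsets for per-slice (2-D) operations
conn_offsets_2d <- function(connectivity = 8L, slice_axis = 3L) {
  if (!connectivity %in% c(4L, 8L))
    stop("2-D connectivity must be 4 or 8", call. = FALSE)
  off <- conn_offsets_3d(if (connectivity == 4L) 6L else 26L)
  off[off[, slice_axis] == 0L, , drop = FALSE]
}

# sum of the mask shifted by every offset; out-of-border voxels contribute 0
shift_accumulate <- function(bin, offsets) {
  d <- dim(bin)
  m <- array(as.integer(bin), d)
  acc <- array(0L, d)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    idx_src <- vector("list", 3L)
    idx_dst <- vector("list", 3L)
    feasible <- TRUE
    for (ax in 1:3) {
      n <- d[ax]; k <- o[ax]
      if (abs(k) >= n) { feasible <- FALSE; break }
      if (k >= 0) { idx_src[[ax]] <- seq_len(n - k); idx_dst[[ax]] <- (k + 1):n }
      else        { idx_src[[ax]] <- (1 - k):n;      idx_dst[[ax]] <- seq_len(n + k) }
    }
    if (!feasible) next
    acc[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      acc[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  acc
}

#' Binary erosion
#'
#' Standard binary erosion with the volume exterior treated as background;
#' the result is a subset of the input. In the pipeline this both removes
#' speckle noise and detaches thin bridges (vessels, fibrous tissue) that
#' wrongly connect neighbouring structures.
#'
#' @param mask A binary [label_mask()].
#' @param elem A [struct_element()].
#' @return A binary [label_mask()].
#' @export
erode <- function(mask, elem = struct_element("ball", 2L)) {
  bin <- as_binary(mask)
  acc <- shift_accumulate(bin, elem$offsets)
  with_labels(mask, acc == nrow(elem$offsets))
}

#' Binary dilation
#'
#' Standard binary dilation; the input is a subset of the result. In the
#' pipeline it compensates the preceding erosion and re-joins broken parts
#' of the same structure.
#'
#' @inheritParams erode
#' @return A binary [label_mask()].
#' @export
dilate <- function(mask, elem = struct_element("ball", 2L)) {
  bin <- as_binary(mask)
  acc <- shift_accumulate(bin, elem$offsets)
  with_labels(mask, acc > 0L)
}

#' Fill interior cavities of a binary mask
#'
#' Background components with no path (6-connectivity on the background) to
#' the volume border are set to foreground. This recovers low-density
#' interior regions such as the lymph-node hilum, which the density
#' clustering necessarily excludes.
#'
#' @param mask A binary [label_mask()].
#' @return A binary [label_mask()]; the input is a subset of the result.
#' @export
fill_holes <- function(mask) {
  bin <- as_binary(mask)
  bg <- !bin
  lab <- .label_components_cpp(bg, dim(bg), conn_offsets_3d(6L))
  d <- dim(bg)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border != 0L]
  holes <- bg & !(lab %in% border)
  dim(holes) <- d
  with_labels(mask, bin | holes)
}

#' Remove small features slice-by-slice
#'
#' On every 2-D slice orthogonal to `slice_axis`, connected components with
#' fewer than `min_pixels` pixels are removed (2-D noise removal).
#'
#' @param mask A binary [label_mask()].
#' @param min_pixels Minimum surviving component size, in pixels (>= 1).
#' @param slice_axis Axis orthogonal to the slices (default 3, axial).
#' @param connectivity 2-D connectivity, 4 or 8 (default 8).
#' @return A binary [label_mask()].
#' @export
filter_small_2d <- function(mask, min_pixels, slice_axis = 3L,
                            connectivity = 8L) {
  stopifnot(min_pixels >= 1)
  if (min_pixels == 1) return(with_labels(mask, as_binary(mask)))
  bin <- as_binary(mask)
  # in-plane offsets only: components can never span slices, so one 3-D
  # labelling pass labels every slice at once
  lab <- .label_components_cpp(bin, dim(bin), conn_offsets_2d(connectivity, slice_axis))
  drop_small_components(mask, bin, lab, min_pixels)
}

#' Remove small features in 3-D
#'
#' Connected components of the full 3-D mask with fewer than `min_voxels`
#' voxels are removed (3-D noise removal).
#'
#' @param mask A binary [label_mask()].
#' @param min_voxels Minimum surviving component volume, in voxels (>= 1).
#' @param connectivity 3-D connectivity, 6, 18 or 26 (default 26).
#' @return A binary [label_mask()].
#' @export
filter_small_3d <- function(mask, min_voxels, connectivity = 26L) {
  stopifnot(min_voxels >= 1)
  if (min_voxels == 1) return(with_labels(mask, as_binary(mask)))
  bin <- as_binary(mask)
  lab <- .label_components_cpp(bin, dim(bin), conn_offsets_3d(connectivity))
  drop_small_components(mask, bin, lab, min_voxels)
}

drop_small_components <- function(mask, bin, lab, min_size) {
  if (!any(bin)) return(with_labels(mask, bin))
  sizes <- tabulate(lab)
  keep_lab <- which(sizes >= min_size)
  keep <- bin & (lab %in% keep_lab)
  dim(keep) <- dim(bin)
  with_labels(mask, keep)
}

#' Label connected components deterministically
#'
#' Foreground components are labelled `1..C`, ordered by each component's
#' minimal voxel position in column-major scan order (fastest along the
#' first axis), so the labelling is reproducible across platforms.
#'
#' @param mask A binary [label_mask()].
#' @param connectivity 3-D connectivity, 6, 18 or 26 (default 26).
#' @return A [label_mask()] with component labels `1..C`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  bin <- as_binary(mask)
  lab <- .label_components_cpp(bin, dim(bin), conn_offsets_3d(connectivity))
  with_labels(mask, lab)
}

count_components <- function(bin, connectivity = 26L) {
  max(.label_components_cpp(bin, dim(bin), conn_offsets_3d(connectivity)), 0L)
}

#' Cylindrical specimen-case geometry
#'
#' Describes the cylindrical specimen container as seen by the scanner: its
#' axis (a grid axis), the world-mm position of the axis in the orthogonal
#' plane, the inner radius, and a safety margin stripped inside the wall.
#'
#' @param axis Grid axis of the cylinder (1, 2 or 3).
#' @param center Length-2 world-mm coordinates of the cylinder axis in the
#'   plane orthogonal to `axis` (ordered by the two remaining axes).
#' @param radius Inner case radius, mm.
#' @param margin Band inside the wall to strip, mm (`radius > margin >= 0`).
#' @return A list of class `case_geometry`.
#' @export
case_geometry <- function(axis = 3L, center = c(0, 0), radius, margin = 0.5) {
  if (radius <= margin || margin < 0)
    stop(sprintf("degenerate case geometry: need radius > margin >= 0 (radius = %g, margin = %g)",
                 radius, margin), call. = FALSE)
  structure(list(axis = as.integer(axis), center = as.numeric(center),
                 radius = radius, margin = margin),
            class = "case_geometry")
}

#' Remove the specimen case by geometric distance
#'
#' Voxels whose radial world-distance from the cylinder axis is at least
#' `radius - margin` are set to background; all other voxels are unchanged.
#' This strips the container wall (and wall-adjacent misclassifications)
#' from the node mask.
#'
#' @param mask A binary [label_mask()].
#' @param geom A [case_geometry()].
#' @return A binary [label_mask()].
#' @export
remove_case <- function(mask, geom) {
  stopifnot(inherits(geom, "case_geometry"))
  d <- grid_size(mask)
  plane_axes <- setdiff(1:3, geom$axis)
  u <- axis_world_coords(mask, plane_axes[1]) - geom$center[1]
  v <- axis_world_coords(mask, plane_axes[2]) - geom$center[2]
  keep2 <- outer(u^2, v^2, `+`) < (geom$radius - geom$margin)^2
  keep3 <- expand_plane(keep2, d, geom$axis)
  with_labels(mask, as_binary(mask) & keep3)
}

# broadcast a 2-D plane (over the axes orthogonal to `axis`) to the 3-D grid
expand_plane <- function(plane, d, axis) {
  out <- switch(axis,
                array(rep(plane, each = d[1]), d),            # plane is d2 x d3
                aperm(array(plane, c(d[1], d[3], d[2])), c(1, 3, 2)), # d1 x d3
                array(plane, d))                              # d1 x d2
  out
}

#' Estimate the specimen-case geometry from a non-air mask
#'
#' Best-effort estimator: projects the non-air voxels onto the plane
#' orthogonal to `axis`, takes the bounding-box centre as the cylinder axis
#' position and the maximum radial distance as the radius. Intended as a
#' fallback when the container geometry is not supplied; always overridable
#' via the pipeline configuration.
#'
#' @param nonair A binary [label_mask()] of non-air voxels (e.g. clusters
#'   with rank above air).
#' @param axis Cylinder axis (default 3).
#' @param margin Margin to carry into the returned geometry, mm.
#' @return A [case_geometry()].
#' @export
estimate_case_geometry <- function(nonair, axis = 3L, margin = 0.5) {
  bin <- as_binary(nonair)
  if (!any(bin)) stop("cannot estimate case geometry from an empty mask",
                      call. = FALSE)
  plane_axes <- setdiff(1:3, axis)
  pres <- apply(bin, plane_axes, any)
  u <- axis_world_coords(nonair, plane_axes[1])
  v <- axis_world_coords(nonair, plane_axes[2])
  iu <- range(which(apply(pres, 1, any)))
  iv <- range(which(apply(pres, 2, any)))
  center <- c(mean(u[iu]), mean(v[iv]))
  du <- u - center[1]; dv <- v - center[2]
  r2 <- outer(du^2, dv^2, `+`)
  radius <- sqrt(max(r2[pres]))
  case_geometry(axis = axis, center = center, radius = radius, margin = margin)
}
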