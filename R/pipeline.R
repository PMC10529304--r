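# End-to-end CT-based nodal segmentation. The stage order is fixed:
#   k-means clustering -> fat/air removal (binary node mask) -> case removal
#   -> erosion -> hole-filling -> 2-D small-feature removal -> dilation
#   -> 3-D small-feature removal -> connected-component labelling.
# Equal erosion and dilation radii are the default so that the dilation
# compensates the erosion; every radius, threshold and connectivity is
# exposed in the configuration because none of them is dictated by the
# method itself — they are tuned on phantoms.

#' Segmentation pipeline configuration
#'
#' All tunables of the CT-based nodal segmentation in one object. Defaults
#' are calibrated for specimen CT at 0.1 mm spacing.
#'
#' @param clustering A [clustering_config()].
#' @param case A [case_geometry()], or `"auto"` to estimate the container
#'   cylinder from the non-air clusters ([estimate_case_geometry()]), or
#'   `"none"` to skip case removal.
#' @param case_margin Margin (mm) stripped inside the case wall when `case`
#'   is `"auto"`.
#' @param erosion_radius,dilation_radius Structuring-element radii in
#'   voxels (>= 1); equal by default so dilation compensates erosion.
#' @param element Structuring-element shape, `"ball"` or `"cube"`.
#' @param min_pixels_2d Minimum 2-D component size kept per slice (pixels).
#' @param min_voxels_3d Minimum 3-D component volume kept (voxels).
#' @param connectivity_2d 2-D connectivity (4 or 8).
#' @param connectivity_3d 3-D connectivity (6, 18 or 26).
#' @param slice_axis Axis orthogonal to the 2-D filtering slices.
#' @param fill_2d Logical; fill holes slice-wise instead of in 3-D. The
#'   default fills in 3-D, treating the hilum as a 3-D cavity.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(clustering = clustering_config(),
                                case = "auto",
                                case_margin = 0.5,
                                erosion_radius = 2L,
                                dilation_radius = 2L,
                                element = c("ball", "cube"),
                                min_pixels_2d = 20L,
                                min_voxels_3d = 500L,
                                connectivity_2d = 8L,
                                connectivity_3d = 26L,
                                slice_axis = 3L,
                                fill_2d = FALSE) {
  element <- match.arg(element)
  stopifnot(erosion_radius >= 1, dilation_radius >= 1,
            min_pixels_2d >= 1, min_voxels_3d >= 1)
  if (!(is.character(case) && case %in% c("auto", "none")) &&
      !inherits(case, "case_geometry"))
    stop("case must be a case_geometry, \"auto\" or \"none\"", call. = FALSE)
  structure(list(clustering = clustering, case = case,
                 case_margin = case_margin,
                 erosion_radius = as.integer(erosion_radius),
                 dilation_radius = as.integer(dilation_radius),
                 element = element,
                 min_pixels_2d = as.integer(min_pixels_2d),
                 min_voxels_3d = as.integer(min_voxels_3d),
                 connectivity_2d = as.integer(connectivity_2d),
                 connectivity_3d = as.integer(connectivity_3d),
                 slice_axis = as.integer(slice_axis),
                 fill_2d = isTRUE(fill_2d)),
            class = "segmentation_config")
}

#' Segment nodal structures in a specimen CT volume
#'
#' Runs the full CT-based segmentation: 1-D k-means tissue clustering,
#' extraction of the node cluster, geometric case removal, erosion,
#' hole-filling, slice-wise small-feature removal, dilation, volumetric
#' small-feature removal, and deterministic component labelling. An empty
#' final mask is a valid result (zero components), not an error: the tool
#' must distinguish "no nodes found" from failure.
#'
#' @param ct A [volume_grid()] of CT attenuation.
#' @param config A [segmentation_config()].
#' @param keep_stage_masks Logical; retain the intermediate binary mask of
#'   every stage in the trace (memory-heavy, intended for audits).
#' @return A list with `mask` (a [label_mask()] of node components labelled
#'   `1..C`), `trace` (data frame of per-stage foreground voxel and
#'   component counts, in execution order), `model` (the fitted
#'   `cluster_model`), `case` (the [case_geometry()] used, or `NULL`), and
#'   optionally `stage_masks`.
#' @export
segment_nodes <- function(ct, config = segmentation_config(),
                          keep_stage_masks = FALSE) {
  stopifnot(inherits(ct, "volume_grid"),
            inherits(config, "segmentation_config"))
  conn3 <- config$connectivity_3d
  stages <- character(); voxels <- integer(); comps <- integer()
  stage_masks <- if (keep_stage_masks) list() else NULL
  note <- function(name, mask) {
    stages <<- c(stages, name)
    bin <- as_binary(mask)
    voxels <<- c(voxels, sum(bin))
    comps <<- c(comps, count_components(bin, conn3))
    if (keep_stage_masks) stage_masks[[name]] <<- mask
    mask
  }

  model <- fit_kmeans_1d(ct$values, config$clustering)
  clusters <- assign_clusters(ct, model)
  mask <- note("node_cluster", extract_node_mask(clusters, model))

  geom <- NULL
  if (inherits(config$case, "case_geometry")) {
    geom <- config$case
  } else if (identical(config$case, "auto")) {
    nonair <- with_labels(clusters, clusters$labels > model$tissue_roles[["air"]])
    geom <- estimate_case_geometry(nonair, margin = config$case_margin)
  }
  if (!is.null(geom)) mask <- note("case_removed", remove_case(mask, geom))

  se_er <- struct_element(config$element, config$erosion_radius)
  se_di <- struct_element(config$element, config$dilation_radius)
  mask <- note("eroded", erode(mask, se_er))
  mask <- note("filled", if (config$fill_2d) fill_holes_2d(mask, config$slice_axis)
                         else fill_holes(mask))
  mask <- note("filtered_2d", filter_small_2d(mask, config$min_pixels_2d,
                                              config$slice_axis,
                                              config$connectivity_2d))
  mask <- note("dilated", dilate(mask, se_di))
  mask <- note("filtered_3d", filter_small_3d(mask, config$min_voxels_3d, conn3))
  final <- note("labelled", label_components(mask, conn3))

  out <- list(mask = final,
              trace = data.frame(stage = stages, voxels = voxels,
                                 components = comps),
              model = model, case = geom)
  if (keep_stage_masks) out$stage_masks <- stage_masks
  out
}

# slice-wise hole filling (configuration switch); fills 2-D cavities per
# slice orthogonal to `slice_axis`
fill_holes_2d <- function(mask, slice_axis = 3L) {
  bin <- as_binary(mask)
  bg <- !bin
  lab <- .label_components_cpp(bg, dim(bg), conn_offsets_2d(4L, slice_axis))
  d <- dim(bg)
  # border of each slice: all faces except those orthogonal to slice_axis
  faces <- list(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])])
  border <- unique(unlist(faces[setdiff(1:3, slice_axis)]))
  border <- border[border != 0L]
  holes <- bg & !(lab %in% border)
  dim(holes) <- d
  with_labels(mask, bin | holes)
}

#' Run the segmentation from files
#'
#' Reads a CT volume and a YAML configuration, runs [segment_nodes()], and
#' writes the labelled node mask (and optionally the stage trace as JSON).
#'
#' @param ct_path Path to the CT NIfTI volume.
#' @param config_path Path to a YAML pipeline configuration, or `NULL` for
#'   defaults (see [read_pipeline_config()]).
#' @param out_mask_path Output path for the labelled node mask.
#' @param trace_path Optional output path for the JSON stage trace.
#' @return The stage trace data frame, invisibly.
#' @export
run_from_files <- function(ct_path, config_path = NULL, out_mask_path,
                           trace_path = NULL) {
  ct <- read_volume(ct_path)
  config <- if (is.null(config_path)) segmentation_config() else
    read_pipeline_config(config_path)
  res <- segment_nodes(ct, config)
  write_mask(res$mask, out_mask_path)
  if (!is.null(trace_path))
    jsonlite::write_json(res$trace, trace_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(res$trace)
}

pipeline_config_keys <- c("clustering", "case", "case_margin",
                          "erosion_radius", "dilation_radius", "element",
                          "min_pixels_2d", "min_voxels_3d",
                          "connectivity_2d", "connectivity_3d",
                          "slice_axis", "fill_2d")
clustering_config_keys <- c("k", "seed", "max_iter", "tol", "n_init",
                            "subsample")

#' Read a pipeline configuration from YAML
#'
#' Every key is optional and defaults to the [segmentation_config()]
#' default; unknown keys are an error naming the key. The `case` entry may
#' be `"auto"`, `"none"`, or a mapping with `axis`, `center`, `radius`,
#' `margin`.
#'
#' @param path Path to a YAML file.
#' @return A [segmentation_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), pipeline_config_keys)
  if (length(bad))
    stop(sprintf("unknown configuration key(s) in '%s': %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  args <- raw
  if (!is.null(raw$clustering)) {
    badc <- setdiff(names(raw$clustering), clustering_config_keys)
    if (length(badc))
      stop(sprintf("unknown clustering key(s) in '%s': %s",
                   path, paste(badc, collapse = ", ")), call. = FALSE)
    args$clustering <- do.call(clustering_config, raw$clustering)
  }
  if (!is.null(raw$case) && is.list(raw$case))
    args$case <- do.call(case_geometry, raw$case)
  do.call(segmentation_config, args)
}
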