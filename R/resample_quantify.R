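# CT-grid masks applied to the PET grid. The CT is reconstructed at 0.1 mm
# and the PET at 0.4 mm, with their own sizes and origins, so the
# segmentation mask must be resampled before PET values can be read out.
# Resampling is nearest-neighbour by construction — a label image admits no
# meaningful interpolation, and nearest-neighbour guarantees no new labels
# are introduced. Because both grids are axis-aligned the lookup is
# separable: each target axis maps independently to a source index.

#' Resample a label mask onto another grid by nearest neighbour
#'
#' Each target voxel takes the label of the source voxel whose centre is
#' nearest to the target voxel's world centre (ties go to the lower source
#' index). Target voxels outside the source field of view become
#' background. The output label set is always a subset of the source label
#' set; this is asserted on every call.
#'
#' @param mask A [label_mask()] (source).
#' @param target A `volume_grid` or `label_mask` supplying the target
#'   geometry, or a list with `size`, `spacing`, `origin`.
#' @return A [label_mask()] on the target geometry.
#' @export
resample_mask <- function(mask, target) {
  stopifnot(inherits(mask, "label_mask"))
  tg <- as_target_geometry(target)
  src_d <- grid_size(mask)
  idx <- vector("list", 3L)
  ok <- vector("list", 3L)
  for (ax in 1:3) {
    w <- tg$origin[ax] + (seq_len(tg$size[ax]) - 1) * tg$spacing[ax]
    x <- (w - mask$origin[ax]) / mask$spacing[ax]
    # nearest source index (0-based); exact half-way ties -> lower index.
    # The source field of view is the closed interval extending half a
    # voxel beyond the first and last centres.
    i <- pmax(ceiling(x - 0.5), 0L)
    ok[[ax]] <- x >= -0.5 & x <= src_d[ax] - 0.5
    idx[[ax]] <- i + 1L
  }
  out <- array(0L, tg$size)
  if (all(vapply(ok, any, logical(1)))) {
    vx <- which(ok[[1]]); vy <- which(ok[[2]]); vz <- which(ok[[3]])
    out[vx, vy, vz] <- mask$labels[idx[[1]][vx], idx[[2]][vy], idx[[3]][vz],
                                   drop = FALSE]
  } else {
    warning("source and target grids do not overlap; returning an all-background mask",
            call. = FALSE)
  }
  res <- label_mask(out, spacing = tg$spacing, origin = tg$origin)
  new_labels <- setdiff(mask_labels(res), mask_labels(mask))
  if (length(new_labels))
    stop("internal error: resampling introduced new labels", call. = FALSE)
  res
}

as_target_geometry <- function(target) {
  if (inherits(target, "volume_grid") || inherits(target, "label_mask"))
    return(list(size = grid_size(target), spacing = target$spacing,
                origin = target$origin))
  stopifnot(is.list(target), all(c("size", "spacing", "origin") %in% names(target)))
  list(size = as.integer(target$size), spacing = as.numeric(target$spacing),
       origin = as.numeric(target$origin))
}

#' Maximum standardized uptake value over a labelled region
#'
#' @param pet A [volume_grid()] of SUV values.
#' @param mask A [label_mask()] with the same geometry as `pet`.
#' @param label The node component label to read out.
#' @return The maximum PET value over the label's voxels.
#' @export
suvmax <- function(pet, mask, label) {
  stopifnot(inherits(pet, "volume_grid"), inherits(mask, "label_mask"))
  if (!same_geometry(pet, mask))
    stop("PET volume and mask geometries differ; resample the mask first",
         call. = FALSE)
  sel <- mask$labels == as.integer(label)
  if (!any(sel))
    stop(sprintf("label %s not present in mask; available labels: %s",
                 label, paste(mask_labels(mask), collapse = ", ")),
         call. = FALSE)
  max(pet$values[sel])
}

#' Target-to-background ratio
#'
#' TBR = SUVmax of the target region divided by the background SUVmax.
#' The ratio is returned at full precision; use [round_report()] for the
#' 1-decimal presentation used in reports.
#'
#' @param suvmax_value Target SUVmax (>= 0).
#' @param background_suvmax Background SUVmax (> 0).
#' @return The ratio, full precision.
#' @examples
#' round_report(tbr(5.9, 1.7), 1)  # 3.5
#' @export
tbr <- function(suvmax_value, background_suvmax) {
  if (background_suvmax <= 0)
    stop("background SUVmax must be positive", call. = FALSE)
  suvmax_value / background_suvmax
}

#' Round half away from zero for report display
#'
#' Report tables print TBR to 1 decimal and segmentation metrics to 2
#' decimals, rounding halves away from zero; values are always stored at
#' full precision internally.
#'
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded numeric.
#' @export
round_report <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Background SUVmax from non-target regions
#'
#' Default strategy: the maximum PET value over specimen voxels outside the
#' node mask dilated by a safety margin. The specimen region is supplied
#' explicitly (`region`), or defaults to voxels with positive uptake (the
#' scanner records essentially no activity outside the specimen). An
#' explicit background ROI mask overrides the strategy entirely.
#'
#' @param pet A [volume_grid()] of SUV values.
#' @param node_mask A [label_mask()] aligned with `pet`.
#' @param roi Optional explicit background ROI ([label_mask()], non-zero =
#'   ROI); if given, the result is the PET maximum over the ROI.
#' @param region Optional [label_mask()] delimiting the specimen interior;
#'   default: voxels with PET value > 0.
#' @param margin_mm Dilation margin (mm) applied to the node mask before
#'   exclusion.
#' @return Background SUVmax (a scalar).
#' @export
background_suvmax <- function(pet, node_mask, roi = NULL, region = NULL,
                              margin_mm = 1) {
  stopifnot(inherits(pet, "volume_grid"))
  if (!is.null(roi)) {
    if (!same_geometry(pet, roi)) stop("ROI geometry differs from PET",
                                       call. = FALSE)
    sel <- roi$labels != 0L
    if (!any(sel)) stop("background ROI is empty", call. = FALSE)
    return(max(pet$values[sel]))
  }
  if (!same_geometry(pet, node_mask))
    stop("node mask geometry differs from PET; resample first", call. = FALSE)
  rad <- max(1L, as.integer(ceiling(margin_mm / min(pet$spacing))))
  grown <- dilate(node_mask, struct_element("ball", rad))
  reg <- if (is.null(region)) pet$values > 0 else region$labels != 0L
  sel <- reg & !as_binary(grown)
  if (!any(sel))
    stop("background region is empty after excluding the dilated node mask",
         call. = FALSE)
  max(pet$values[sel])
}

#' Semi-quantify every node on the PET volume
#'
#' Applies a (CT-derived) node mask to the PET volume and computes, per
#' node label: voxel count on the PET grid, SUVmax, background SUVmax, and
#' TBR. If the mask geometry differs from the PET geometry it is resampled
#' by nearest neighbour first.
#'
#' @param pet A [volume_grid()] of SUV values.
#' @param mask A [label_mask()] of node components (any geometry).
#' @param roi,region,margin_mm Passed to [background_suvmax()].
#' @return A data frame with columns `label`, `voxels`, `suvmax`,
#'   `background_suvmax`, `tbr` (full precision), one row per label;
#'   zero rows for an empty mask.
#' @export
quantify <- function(pet, mask, roi = NULL, region = NULL, margin_mm = 1) {
  stopifnot(inherits(pet, "volume_grid"), inherits(mask, "label_mask"))
  if (!same_geometry(pet, mask)) mask <- resample_mask(mask, pet)
  labs <- mask_labels(mask)
  if (length(labs) == 0L)
    return(data.frame(label = integer(), voxels = integer(),
                      suvmax = numeric(), background_suvmax = numeric(),
                      tbr = numeric()))
  bg <- background_suvmax(pet, mask, roi = roi, region = region,
                          margin_mm = margin_mm)
  sm <- vapply(labs, function(l) suvmax(pet, mask, l), numeric(1))
  nv <- vapply(labs, function(l) sum(mask$labels == l), integer(1))
  data.frame(label = labs, voxels = nv, suvmax = sm,
             background_suvmax = bg, tbr = sm / bg)
}

#' Body-weight standardized uptake value
#'
#' SUV = activity concentration (Bq/mL) divided by injected dose per body
#' mass, with tissue density taken as 1 g/mL:
#' `SUV = conc * weight_kg * 1000 / (dose_MBq * 1e6)`.
#'
#' @param activity_conc Activity concentration, Bq/mL.
#' @param injected_dose Injected dose, MBq (> 0).
#' @param body_weight Body weight, kg (> 0).
#' @return SUV (dimensionless).
#' @export
suv_scale <- function(activity_conc, injected_dose, body_weight) {
  if (injected_dose <= 0) stop("injected dose must be positive", call. = FALSE)
  if (body_weight <= 0) stop("body weight must be positive", call. = FALSE)
  activity_conc * (body_weight * 1000) / (injected_dose * 1e6)
}
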