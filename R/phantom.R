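# Synthetic specimen phantom. Emulates the scene the segmentation assumes:
# a cylindrical specimen container filled with fat-density tissue, air
# outside, ellipsoidal soft-tissue nodes (optionally with a low-density
# hilum and thin vessel bridges touching the node surface), and a paired
# PET volume on its own coarser grid with elevated nodal uptake over a
# uniform specimen background. Intensities are abstract attenuation units:
# only the density ordering air < hilum <= fat < node matters to the
# method, mirroring a CT-like scale (air -1000, fat -100, soft tissue +40).
#
# The PET uptake profile inside each node is a truncated Gaussian radial
# falloff whose centre voxel is pinned at the configured peak (and node
# voxels are clipped at the peak), so SUVmax is analytically known and
# quantification tests have exact expectations.

#' Specify a synthetic specimen phantom
#'
#' Defaults describe the "easy" reference phantom: a 160^3 grid at 0.1 mm
#' (16 mm cube), a 6.5 mm-radius case with a 0.3 mm wall, and three
#' well-separated spherical nodes of 1.5 mm radius with high fat/node
#' contrast (140 attenuation units = 7 noise SDs).
#'
#' @param size Integer length-3 CT grid size (voxels).
#' @param spacing CT voxel spacing, mm.
#' @param case_radius Inner case radius, mm.
#' @param case_wall Case wall thickness, mm.
#' @param mean_air,mean_fat,mean_node,mean_vessel,mean_case Tissue mean
#'   attenuations; must satisfy air < hilum <= fat < node.
#' @param ct_noise_sd Gaussian CT noise SD (attenuation units).
#' @param n_nodes Number of nodes (>= 0).
#' @param semi_axes_range Length-2 range (mm) from which each ellipsoid
#'   semi-axis is drawn; a degenerate range gives equal spheres.
#' @param min_separation Minimum surface-to-surface separation between
#'   nodes, mm.
#' @param hilum Logical; carve a low-density hilum into each node.
#' @param hilum_rel Hilum semi-axes relative to the node's (0-1).
#' @param mean_hilum Hilum mean attenuation (between air and fat).
#' @param vessel_bridges Number of nodes given a thin vessel bridge
#'   touching their surface.
#' @param vessel_radius,vessel_length Vessel tube radius and length, mm.
#' @param pet_background Specimen background uptake (SUV).
#' @param pet_peak Node peak uptake (SUV).
#' @param pet_noise_sd PET noise SD (SUV); noise is clipped at
#'   `pet_noise_clip` SDs so background SUVmax is bounded.
#' @param pet_noise_clip Clip, in SDs.
#' @param pet_spacing PET voxel spacing, mm.
#' @param seed RNG seed; the phantom is bit-reproducible given the seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(160L, 160L, 160L),
                         spacing = c(0.1, 0.1, 0.1),
                         case_radius = 6.5, case_wall = 0.3,
                         mean_air = -1000, mean_fat = -100,
                         mean_node = 40, mean_vessel = 40, mean_case = 100,
                         ct_noise_sd = 20,
                         n_nodes = 3L,
                         semi_axes_range = c(1.5, 1.5),
                         min_separation = 2,
                         hilum = FALSE, hilum_rel = 0.35, mean_hilum = -300,
                         vessel_bridges = 0L,
                         vessel_radius = 0.25, vessel_length = 2,
                         pet_background = 1.5, pet_peak = 8,
                         pet_noise_sd = 0.05, pet_noise_clip = 3,
                         pet_spacing = c(0.4, 0.4, 0.4),
                         seed = 0L) {
  if (!(mean_air < mean_hilum && mean_hilum <= mean_fat && mean_fat < mean_node))
    stop("tissue intensities must be ordered air < hilum <= fat < node",
         call. = FALSE)
  stopifnot(n_nodes >= 0, all(semi_axes_range > 0), min_separation >= 0,
            case_radius > 0, case_wall > 0, ct_noise_sd >= 0,
            pet_background > 0, pet_peak >= pet_background)
  structure(list(size = as.integer(size), spacing = as.numeric(spacing),
                 case_radius = case_radius, case_wall = case_wall,
                 mean_air = mean_air, mean_fat = mean_fat,
                 mean_node = mean_node, mean_vessel = mean_vessel,
                 mean_case = mean_case, ct_noise_sd = ct_noise_sd,
                 n_nodes = as.integer(n_nodes),
                 semi_axes_range = as.numeric(semi_axes_range),
                 min_separation = min_separation,
                 hilum = isTRUE(hilum), hilum_rel = hilum_rel,
                 mean_hilum = mean_hilum,
                 vessel_bridges = as.integer(vessel_bridges),
                 vessel_radius = vessel_radius, vessel_length = vessel_length,
                 pet_background = pet_background, pet_peak = pet_peak,
                 pet_noise_sd = pet_noise_sd, pet_noise_clip = pet_noise_clip,
                 pet_spacing = as.numeric(pet_spacing),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# deterministic sub-seed per node index, kept inside 32-bit range
node_seed <- function(seed, i) (abs(seed) + 7919 * i) %% 2147483647

place_nodes <- function(spec) {
  if (spec$n_nodes == 0L)
    return(data.frame(label = integer(), cx = numeric(), cy = numeric(),
                      cz = numeric(), a = numeric(), b = numeric(),
                      c = numeric()))
  zext <- (spec$size[3] - 1) * spec$spacing[3] / 2
  placed <- list()
  for (i in seq_len(spec$n_nodes)) {
    set.seed(node_seed(spec$seed, i))
    done <- FALSE
    for (attempt in seq_len(10000L)) {
      ax <- sort(runif(3, spec$semi_axes_range[1], spec$semi_axes_range[2]),
                 decreasing = TRUE)
      amax <- ax[1]
      rmax <- spec$case_radius - amax - 1.0  # clearance from wall + margin band
      if (rmax <= 0)
        stop("nodes do not fit inside the case: semi-axes too large",
             call. = FALSE)
      rr <- sqrt(runif(1)) * rmax
      th <- runif(1, 0, 2 * pi)
      cand <- c(rr * cos(th), rr * sin(th),
                runif(1, -zext + amax + 0.5, zext - amax - 0.5))
      ok <- TRUE
      for (p in placed) {
        gap <- sqrt(sum((cand - c(p$cx, p$cy, p$cz))^2)) - amax - max(p$a, p$b, p$c)
        if (gap < spec$min_separation) { ok <- FALSE; break }
      }
      if (ok) {
        placed[[i]] <- list(cx = cand[1], cy = cand[2], cz = cand[3],
                            a = ax[1], b = ax[2], c = ax[3])
        done <- TRUE
        break
      }
    }
    if (!done)
      stop(sprintf("could not place node %d with separation %g mm after 10000 attempts",
                   i, spec$min_separation), call. = FALSE)
  }
  cbind(data.frame(label = seq_len(spec$n_nodes)),
        do.call(rbind, lapply(placed, as.data.frame)))
}

# set `value` inside the ellipsoid, restricted to its bounding box
paint_ellipsoid <- function(arr, xs, ys, zs, center, semi, value) {
  ix <- which(abs(xs - center[1]) <= semi[1])
  iy <- which(abs(ys - center[2]) <= semi[2])
  iz <- which(abs(zs - center[3]) <= semi[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(arr)
  u <- (xs[ix] - center[1]) / semi[1]
  v <- (ys[iy] - center[2]) / semi[2]
  w <- (zs[iz] - center[3]) / semi[3]
  rho2 <- outer(outer(u^2, v^2, `+`), w^2, `+`)
  sub <- arr[ix, iy, iz, drop = FALSE]
  sub[rho2 <= 1] <- value
  arr[ix, iy, iz] <- sub
  arr
}

#' Generate a synthetic specimen phantom
#'
#' Builds the CT volume, the paired PET volume on its own (coarser) grid,
#' the ground-truth node mask (hilum voxels carry the node's label), and a
#' placement record. Fully deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `ct` ([volume_grid()]), `pet` ([volume_grid()]),
#'   `truth` ([label_mask()] on the CT grid), `meta` (data frame of node
#'   centres and semi-axes, mm), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)

  d <- spec$size
  origin <- -(d - 1) * spec$spacing / 2  # grid centred on the cylinder axis
  xs <- origin[1] + (seq_len(d[1]) - 1) * spec$spacing[1]
  ys <- origin[2] + (seq_len(d[2]) - 1) * spec$spacing[2]
  zs <- origin[3] + (seq_len(d[3]) - 1) * spec$spacing[3]

  r2 <- outer(xs^2, ys^2, `+`)
  tissue <- array(spec$mean_air, d)
  interior2 <- array(r2 < spec$case_radius^2, c(d[1], d[2]))
  wall2 <- array(r2 >= spec$case_radius^2 &
                   r2 < (spec$case_radius + spec$case_wall)^2, c(d[1], d[2]))
  tissue[array(interior2, d)] <- spec$mean_fat
  tissue[array(wall2, d)] <- spec$mean_case

  meta <- place_nodes(spec)
  truth <- array(0L, d)
  for (i in seq_len(nrow(meta))) {
    m <- meta[i, ]
    cen <- c(m$cx, m$cy, m$cz); semi <- c(m$a, m$b, m$c)
    tissue <- paint_ellipsoid(tissue, xs, ys, zs, cen, semi, spec$mean_node)
    truth <- paint_ellipsoid(truth, xs, ys, zs, cen, semi, m$label)
    if (spec$vessel_bridges >= i) {
      # thin tube along +x, touching the node surface
      ixv <- which(xs >= m$cx + m$a - 2 * spec$spacing[1] &
                     xs <= m$cx + m$a + spec$vessel_length)
      iyv <- which(abs(ys - m$cy) <= spec$vessel_radius)
      izv <- which(abs(zs - m$cz) <= spec$vessel_radius)
      if (length(ixv) && length(iyv) && length(izv)) {
        tub2 <- outer((ys[iyv] - m$cy)^2, (zs[izv] - m$cz)^2, `+`)
        sub <- tissue[ixv, iyv, izv, drop = FALSE]
        inside <- aperm(array(tub2 <= spec$vessel_radius^2,
                              c(length(iyv), length(izv), length(ixv))),
                        c(3, 1, 2))
        sub[inside] <- spec$mean_vessel
        tissue[ixv, iyv, izv] <- sub
      }
    }
    if (spec$hilum) {
      hsemi <- semi * spec$hilum_rel
      hcen <- cen + c(0.3 * m$a, 0, 0)
      tissue <- paint_ellipsoid(tissue, xs, ys, zs, hcen, hsemi,
                                spec$mean_hilum)
      # hilum voxels keep the node's truth label (already painted above)
    }
  }

  set.seed(spec$seed)
  ct_values <- tissue + array(rnorm(prod(d), 0, spec$ct_noise_sd), d)
  ct <- volume_grid(ct_values, spacing = spec$spacing, origin = origin)
  truth_mask <- label_mask(truth, spacing = spec$spacing, origin = origin)

  # --- PET volume on its own grid, same world extent, centred on the axis ---
  extent <- d * spec$spacing
  pd <- pmax(1L, as.integer(floor(extent / spec$pet_spacing)))
  porigin <- -(pd - 1) * spec$pet_spacing / 2
  px <- porigin[1] + (seq_len(pd[1]) - 1) * spec$pet_spacing[1]
  py <- porigin[2] + (seq_len(pd[2]) - 1) * spec$pet_spacing[2]
  pz <- porigin[3] + (seq_len(pd[3]) - 1) * spec$pet_spacing[3]

  pr2 <- outer(px^2, py^2, `+`)
  uptake <- array(0, pd)
  uptake[array(pr2 < spec$case_radius^2, pd)] <- spec$pet_background
  in_node <- array(FALSE, pd)
  sigma <- 0.5  # Gaussian falloff scale in normalized ellipsoid radius
  for (i in seq_len(nrow(meta))) {
    m <- meta[i, ]
    u <- (px - m$cx) / m$a; v <- (py - m$cy) / m$b; w <- (pz - m$cz) / m$c
    rho2 <- outer(outer(u^2, v^2, `+`), w^2, `+`)
    sel <- rho2 <= 1
    uptake[sel] <- spec$pet_background +
      (spec$pet_peak - spec$pet_background) * exp(-rho2[sel] / (2 * sigma^2))
    in_node <- in_node | sel
  }
  set.seed(node_seed(spec$seed, 0L) + 1L)
  noise <- array(rnorm(prod(pd), 0, spec$pet_noise_sd), pd)
  clip <- spec$pet_noise_clip * spec$pet_noise_sd
  noise <- pmin(pmax(noise, -clip), clip)
  pet_values <- pmax(uptake + noise, 0)
  # node voxels never exceed the configured peak, and each node's nearest
  # grid point to its centre is pinned at the peak: SUVmax is exact
  pet_values[in_node] <- pmin(pet_values[in_node], spec$pet_peak)
  for (i in seq_len(nrow(meta))) {
    m <- meta[i, ]
    ci <- c(which.min(abs(px - m$cx)), which.min(abs(py - m$cy)),
            which.min(abs(pz - m$cz)))
    pet_values[ci[1], ci[2], ci[3]] <- spec$pet_peak
  }
  pet <- volume_grid(pet_values, spacing = spec$pet_spacing, origin = porigin)

  list(ct = ct, pet = pet, truth = truth_mask, meta = meta, spec = spec)
}

#' Deterministic difficulty sweeps of a phantom specification
#'
#' Returns a family of specs varying one difficulty dimension while holding
#' everything else (including the seed) fixed:
#' \describe{
#'   \item{noise}{CT noise SD stepped over `c(5, 20, 50)`.}
#'   \item{density}{fat-node contrast narrowed stepwise by raising the fat
#'     mean over `c(-100, -85, -70)` against the node mean at +40 (contrast
#'     140 / 125 / 110 attenuation units). Raising fat rather than lowering
#'     the node keeps the node cluster above the container wall, so the
#'     sweep degrades tissue discrimination without flipping the cluster
#'     topology.}
#'   \item{overlap}{minimum node separation stepped over `c(2, 1, 0.5)` mm.}
#' }
#'
#' @param spec Base [phantom_spec()].
#' @param dimension One of `"noise"`, `"density"`, `"overlap"`.
#' @return A named list of [phantom_spec()] objects, easiest first.
#' @export
perturb <- function(spec, dimension = c("noise", "density", "overlap")) {
  dimension <- match.arg(dimension)
  alter <- function(field, values) {
    out <- lapply(values, function(v) { s <- spec; s[[field]] <- v; s })
    names(out) <- paste0(field, "_", values)
    out
  }
  switch(dimension,
         noise = alter("ct_noise_sd", c(5, 20, 50)),
         density = {
           out <- lapply(c(-100, -85, -70), function(v) {
             s <- spec; s$mean_fat <- v; s
           })
           names(out) <- paste0("fat_mean_", c(-100, -85, -70))
           out
         },
         overlap = alter("min_separation", c(2, 1, 0.5)))
}
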