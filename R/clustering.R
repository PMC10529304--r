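# 1-D k-means over CT attenuation. The three clusters separate the tissue
# classes present in a resected nodal specimen by density: air (lowest
# attenuation), fat, and node/soft tissue (which also captures adjacent
# vessels and fibrotic tissue). Only the ordering of attenuation values
# matters, so no Hounsfield calibration is assumed anywhere.
#
# Lloyd's algorithm in one dimension is implemented on the sorted sample:
# given ascending centroids, each cluster is the contiguous run of values
# between consecutive centroid midpoints, so one iteration costs a handful of
# binary searches plus prefix-sum lookups. A value exactly at a midpoint is
# assigned to the lower cluster (deterministic tie rule, used consistently by
# fitting and by voxel assignment).

#' Clustering configuration
#'
#' @param k Number of clusters (default 3: air, fat, node/soft tissue).
#' @param seed RNG seed for the k-means++ initialization.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param tol Convergence tolerance on the maximum centroid shift
#'   (attenuation units).
#' @param n_init Number of k-means++ restarts; the fit with the lowest
#'   within-cluster sum of squares is kept.
#' @param subsample Optional cap on the number of voxels used to fit the
#'   centroids (`NULL` = use all values). Assignment is always performed on
#'   all voxels.
#' @return A list of class `clustering_config`.
#' @export
clustering_config <- function(k = 3L, seed = 0L, max_iter = 100L, tol = 1e-8,
                              n_init = 5L, subsample = NULL) {
  stopifnot(k >= 1, max_iter >= 1, tol >= 0, n_init >= 1)
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 max_iter = as.integer(max_iter), tol = tol,
                 n_init = as.integer(n_init),
                 subsample = if (is.null(subsample)) NULL else as.integer(subsample)),
            class = "clustering_config")
}

# one Lloyd run from given initial centroids, on a pre-sorted sample
lloyd_1d <- function(sv, csum, init, max_iter, tol) {
  n <- length(sv)
  cen <- sort(init)
  for (it in seq_len(max_iter)) {
    bounds <- (cen[-1] + cen[-length(cen)]) / 2
    # values <= boundary go to the lower cluster
    cut <- c(0L, findInterval(bounds, sv), n)
    newcen <- cen
    for (j in seq_along(cen)) {
      lo <- cut[j]; hi <- cut[j + 1]
      if (hi > lo) newcen[j] <- (csum[hi + 1] - csum[lo + 1]) / (hi - lo)
      # empty cluster: keep previous centroid
    }
    newcen <- sort(newcen)
    shift <- max(abs(newcen - cen))
    cen <- newcen
    if (shift <= tol) break
  }
  bounds <- (cen[-1] + cen[-length(cen)]) / 2
  cut <- c(0L, findInterval(bounds, sv), n)
  ssq <- 0
  for (j in seq_along(cen)) {
    lo <- cut[j]; hi <- cut[j + 1]
    if (hi > lo) {
      seg <- sv[(lo + 1):hi]
      ssq <- ssq + sum((seg - cen[j])^2)
    }
  }
  list(centroids = cen, inertia = ssq)
}

kmeanspp_init <- function(sv, k) {
  n <- length(sv)
  cen <- numeric(k)
  cen[1] <- sv[sample.int(n, 1L)]
  if (k > 1) {
    d2 <- (sv - cen[1])^2
    for (j in 2:k) {
      tot <- sum(d2)
      if (tot <= 0) {
        # all mass already covered; pick any remaining distinct value
        pool <- sv[!(sv %in% cen[seq_len(j - 1)])]
        cen[j] <- pool[sample.int(length(pool), 1L)]
      } else {
        cen[j] <- sv[sample.int(n, 1L, prob = d2 / tot)]
      }
      d2 <- pmin(d2, (sv - cen[j])^2)
    }
  }
  cen
}

#' Fit 1-D k-means to a sample of CT attenuation values
#'
#' Lloyd's algorithm with k-means++ initialization and multiple restarts,
#' keeping the lowest within-cluster sum of squares. Centroids are returned
#' in ascending order and mapped to tissue roles by density rank: for
#' `k = 3`, rank 1 = air, rank 2 = fat, rank 3 = node/soft tissue.
#'
#' @param values Numeric vector (or 3-D array) of attenuation values; at
#'   least `k` distinct values are required.
#' @param config A [clustering_config()].
#' @return A list of class `cluster_model` with `centroids` (ascending),
#'   `inertia` (within-cluster sum of squares on the fitting sample),
#'   `tissue_roles` (named rank mapping when `k = 3`), `k`.
#' @examples
#' m <- fit_kmeans_1d(c(0, 1, 10, 11, 20, 21), clustering_config(k = 3))
#' m$centroids  # 0.5, 10.5, 20.5
#' @export
fit_kmeans_1d <- function(values, config = clustering_config()) {
  v <- as.numeric(values)
  if (anyNA(v) || any(!is.finite(v)))
    stop("attenuation values must be finite", call. = FALSE)
  k <- config$k
  ndist <- length(unique(v))
  if (ndist < k)
    stop(sprintf("need at least k = %d distinct values to fit %d clusters; got %d",
                 k, k, ndist), call. = FALSE)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  if (!is.null(config$subsample) && length(v) > config$subsample)
    v <- v[sample.int(length(v), config$subsample)]

  sv <- sort(v)
  csum <- c(0, cumsum(sv))
  best <- NULL
  for (r in seq_len(config$n_init)) {
    # the first restart is a deterministic quantile-spaced initialization
    # (robust on small samples); the rest are k-means++ draws
    init <- if (r == 1L)
      stats::quantile(sv, probs = (2 * seq_len(k) - 1) / (2 * k),
                      names = FALSE, type = 1)
    else kmeanspp_init(sv, k)
    fit <- lloyd_1d(sv, csum, init, config$max_iter, config$tol)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  roles <- if (k == 3L) c("air", "fat", "node") else
    paste0("rank", seq_len(k))
  structure(list(centroids = best$centroids, inertia = best$inertia,
                 tissue_roles = stats::setNames(seq_len(k), roles), k = k),
            class = "cluster_model")
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Assign every voxel of a CT volume to its nearest cluster
#'
#' Voxels are labelled `1..k` by nearest centroid; a voxel exactly
#' equidistant between two centroids goes to the lower-centroid cluster.
#'
#' @param ct A [volume_grid()] of CT attenuation.
#' @param model A `cluster_model` from [fit_kmeans_1d()].
#' @return A [label_mask()] with labels `1..k` and the geometry of `ct`.
#' @export
assign_clusters <- function(ct, model) {
  stopifnot(inherits(ct, "volume_grid"), inherits(model, "cluster_model"))
  cen <- model$centroids
  if (length(cen) == 1L) {
    lab <- array(1L, grid_size(ct))
  } else {
    bounds <- (cen[-1] + cen[-length(cen)]) / 2
    # value == boundary -> lower cluster, so count strictly-smaller bounds
    lab <- findInterval(ct$values, bounds, left.open = TRUE) + 1L
    lab <- array(as.integer(lab), grid_size(ct))
  }
  label_mask(lab, spacing = ct$spacing, origin = ct$origin)
}

#' Extract the binary node-cluster mask
#'
#' Keeps the highest-density cluster (the node/soft-tissue cluster) and
#' assigns the fat cluster to background, mirroring the construction of a
#' binary two-level mask of the nodal cluster from a 3-cluster model.
#'
#' @param cluster_mask A `1..k` cluster [label_mask()] from
#'   [assign_clusters()].
#' @param model The `cluster_model` that produced it; must have `k = 3`.
#' @return A binary [label_mask()] (1 = node cluster, 0 = air/fat).
#' @export
extract_node_mask <- function(cluster_mask, model) {
  stopifnot(inherits(cluster_mask, "label_mask"),
            inherits(model, "cluster_model"))
  if (model$k != 3L)
    stop(sprintf("node-mask extraction requires a k = 3 (air/fat/node) model; got k = %d",
                 model$k), call. = FALSE)
  node_rank <- model$tissue_roles[["node"]]
  with_labels(cluster_mask, cluster_mask$labels == node_rank)
}
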