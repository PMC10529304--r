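# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# Global 1-D k-means optimum by exhaustive enumeration of contiguous
# partitions of the sorted sample (optimal 1-D clusters are contiguous).
kmeans_1d_exhaustive <- function(v, k) {
  sv <- sort(v)
  n <- length(sv)
  seg_sse <- function(seg) sum((seg - mean(seg))^2)
  if (k == 1) return(seg_sse(sv))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (ci in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, ci], n)
    ssq <- 0
    for (j in seq_len(k)) ssq <- ssq + seg_sse(sv[(b[j] + 1):b[j + 1]])
    if (ssq < best) best <- ssq
  }
  best
}

# Offsets for a given 3-D connectivity (redeclared here so the oracle does
# not depend on package internals).
oracle_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nrm <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nrm == 1, "18" = nrm >= 1 & nrm <= 2, "26" = nrm >= 1)
  g[keep, , drop = FALSE]
}

# Connected components of a logical 3-D array via igraph on the voxel
# adjacency graph; returns a membership vector over foreground voxels in
# linear-index order.
components_igraph <- function(bin, connectivity = 26) {
  d <- dim(bin)
  fg <- which(bin)
  if (length(fg) == 0) return(integer(0))
  coord <- arrayInd(fg, d)
  id <- match(seq_len(prod(d)), fg)  # linear index -> vertex id
  off <- oracle_offsets(connectivity)
  edges <- list()
  for (r in seq_len(nrow(off))) {
    nb <- sweep(coord, 2, off[r, ], `+`)
    okb <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- (nb[okb, 3] - 1) * d[1] * d[2] + (nb[okb, 2] - 1) * d[1] + nb[okb, 1]
    tgt <- id[lin]
    src <- seq_along(fg)[okb]
    keep <- !is.na(tgt)
    edges[[r]] <- cbind(src[keep], tgt[keep])
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
  igraph::components(g)$membership[seq_along(fg)]
}

# Two labelings describe the same partition of the foreground?
same_partition <- function(lab_a, lab_b) {
  length(lab_a) == length(lab_b) &&
    all(tapply(lab_b, lab_a, function(x) length(unique(x))) == 1) &&
    all(tapply(lab_a, lab_b, function(x) length(unique(x))) == 1)
}

# Brute-force nearest-centre resampling oracle on small grids: for every
# target voxel, scan all source centres per axis (ties -> lower index),
# background outside the closed half-voxel field of view.
resample_oracle <- function(mask, target) {
  sd_ <- dim(mask$labels)
  tg <- list(size = nodeseg::grid_size(target), spacing = target$spacing,
             origin = target$origin)
  pick <- function(ax) {
    w <- tg$origin[ax] + (seq_len(tg$size[ax]) - 1) * tg$spacing[ax]
    centers <- mask$origin[ax] + (seq_len(sd_[ax]) - 1) * mask$spacing[ax]
    dmat <- abs(outer(w, centers, `-`))
    i <- apply(dmat, 1, which.min)          # first minimum = lower index
    m <- dmat[cbind(seq_along(w), i)]
    i[m > mask$spacing[ax] / 2 + 1e-12] <- NA
    i
  }
  ix <- pick(1); iy <- pick(2); iz <- pick(3)
  out <- array(0L, tg$size)
  for (a in seq_len(tg$size[1])) for (b in seq_len(tg$size[2]))
    for (cc in seq_len(tg$size[3])) {
      if (!is.na(ix[a]) && !is.na(iy[b]) && !is.na(iz[cc]))
        out[a, b, cc] <- mask$labels[ix[a], iy[b], iz[cc]]
    }
  out
}

# A small, fast phantom for unit tests: 96^3 at 0.1 mm, two 0.9 mm nodes.
# Any field (including the downsized defaults) can be overridden.
small_phantom_spec <- function(seed = 1L, ...) {
  args <- list(size = c(96L, 96L, 96L), case_radius = 3.8, n_nodes = 2L,
               semi_axes_range = c(0.9, 0.9), min_separation = 1.2,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}
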