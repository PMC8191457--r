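# Shared internals for texture-matrix construction.

# The 13 unique 3D directions at Chebyshev distance 1 (one per +/- pair).
directions_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

# All 26 neighbor offsets.
offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
}

# x * log2(x) with 0 log 0 = 0.
xlog2x <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}

# Crop a 3D array to the bounding box of its non-NA voxels. Makes all
# features invariant to where the ROI sits inside a larger volume.
crop_to_roi <- function(a) {
  ok <- !is.na(a)
  if (!any(ok)) stop("empty region: no non-missing voxels")
  w <- which(ok, arr.ind = TRUE)
  rng <- apply(w, 2, range)
  a[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
    drop = FALSE]
}

# Pad with one layer of NA so every interior voxel has 26 in-bounds
# neighbors addressable by a constant linear offset.
pad_na <- function(a) {
  d <- dim(a)
  p <- array(NA_integer_, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2) - 1] <- a
  p
}

# Linear-index offsets of the given voxel offsets in a padded array.
linear_offsets <- function(offs, dim_padded) {
  offs[, 1] + offs[, 2] * dim_padded[1] +
    offs[, 3] * dim_padded[1] * dim_padded[2]
}

# Linear indices (in the padded array) of all non-NA voxels.
padded_core_indices <- function(p) which(!is.na(p))
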