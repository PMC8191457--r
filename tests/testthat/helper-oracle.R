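# Independent brute-force enumerators for texture matrices, written as
# naive coordinate loops with no shared code with the package internals.

oracle_dirs <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    d <- c(dx, dy, dz)
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
      out[[length(out) + 1]] <- d
  }
  out
}

in_bounds <- function(p, dm) all(p >= 1) && all(p <= dm)

# Symmetric co-occurrence counts for one direction.
oracle_glcm <- function(lev, ng, d) {
  dm <- dim(lev)
  m <- matrix(0, ng, ng)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    q <- c(i, j, k) + d
    if (!in_bounds(q, dm)) next
    b <- lev[q[1], q[2], q[3]]
    if (is.na(b)) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  m
}

# Maximal same-level runs along one direction; missing voxels break runs.
oracle_runs <- function(lev, d) {
  dm <- dim(lev)
  runs <- list()
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    p <- c(i, j, k)
    if (in_bounds(p - d, dm)) next  # not a line start
    vals <- c()
    while (in_bounds(p, dm)) {
      vals <- c(vals, lev[p[1], p[2], p[3]])
      p <- p + d
    }
    r <- 0L
    cur <- NA
    for (v in c(vals, NA)) {
      if (!is.na(v) && !is.na(cur) && v == cur) {
        r <- r + 1L
      } else {
        if (!is.na(cur)) runs[[length(runs) + 1]] <- c(cur, r)
        cur <- v
        r <- 1L
      }
    }
  }
  if (!length(runs)) return(data.frame(level = integer(0), length = integer(0)))
  m <- do.call(rbind, runs)
  data.frame(level = m[, 1], length = m[, 2])
}

# 26-connected equal-level zones with Chebyshev distance to the ROI border.
oracle_zones <- function(lev) {
  dm <- dim(lev)
  coords <- which(!is.na(lev), arr.ind = TRUE)
  visited <- array(FALSE, dm)
  cheb_border <- function(p) {
    # smallest d such that some cell within Chebyshev radius d is missing
    for (d in 1:max(dm)) {
      for (dx in -d:d) for (dy in -d:d) for (dz in -d:d) {
        if (max(abs(c(dx, dy, dz))) != d) next
        q <- p + c(dx, dy, dz)
        if (!in_bounds(q, dm) || is.na(lev[q[1], q[2], q[3]])) return(d)
      }
    }
    max(dm)
  }
  zones <- list()
  for (r in seq_len(nrow(coords))) {
    p0 <- coords[r, ]
    if (visited[p0[1], p0[2], p0[3]]) next
    lv <- lev[p0[1], p0[2], p0[3]]
    queue <- list(p0)
    visited[p0[1], p0[2], p0[3]] <- TRUE
    members <- list()
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      members[[length(members) + 1]] <- p
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- p + c(dx, dy, dz)
        if (!in_bounds(q, dm)) next
        if (visited[q[1], q[2], q[3]]) next
        v <- lev[q[1], q[2], q[3]]
        if (is.na(v) || v != lv) next
        visited[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    dmin <- min(vapply(members, cheb_border, numeric(1)))
    zones[[length(zones) + 1]] <- c(lv, length(members), dmin)
  }
  m <- do.call(rbind, zones)
  data.frame(level = m[, 1], size = m[, 2], distance = m[, 3])
}

# Per-voxel neighbour mean (NGTDM) and same-level neighbour count (NGLDM);
# iterates in column-major order to match linear-index ordering.
oracle_neighbours <- function(lev) {
  dm <- dim(lev)
  out <- list()
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    vals <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(i + dx, j + dy, k + dz)
      if (!in_bounds(q, dm)) next
      vals <- c(vals, lev[q[1], q[2], q[3]])
    }
    vals <- vals[!is.na(vals)]
    out[[length(out) + 1]] <- data.frame(
      level = a, n_neigh = length(vals),
      mean_neigh = if (length(vals)) mean(vals) else NA_real_,
      n_same = sum(vals == a))
  }
  do.call(rbind, out)
}

# Random small discretized test volume with missing voxels.
random_disc <- function(dm = c(4, 4, 4), ng = 4, p_missing = 0.25) {
  lev <- array(sample.int(ng, prod(dm), replace = TRUE), dm)
  lev[stats::runif(prod(dm)) < p_missing] <- NA_integer_
  structure(list(levels = lev, n_levels = ng, bin_width = 1,
                 window = c(0, ng)), class = "discretized_volume")
}
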