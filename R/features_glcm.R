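#' Gray-level co-occurrence matrix for one direction
#'
#' Counts symmetric co-occurrences of gray levels between voxel pairs at the
#' given offset (Chebyshev distance 1 in this package). Pairs touching a
#' missing voxel are skipped.
#'
#' @param disc a `discretized_volume`.
#' @param direction integer length-3 offset, e.g. `c(1, 0, 0)`.
#' @return An Ng x Ng symmetric count matrix (not normalized).
#' @export
glcm_matrix <- function(disc, direction) {
  lev <- disc$levels
  ng <- disc$n_levels
  d <- dim(lev)
  src <- lapply(1:3, function(ax) {
    o <- direction[ax]
    seq_len(max(d[ax] - abs(o), 0)) + max(-o, 0)
  })
  if (any(lengths(src) == 0))
    return(matrix(0, ng, ng))
  dst <- lapply(1:3, function(ax) src[[ax]] + direction[ax])
  a <- lev[src[[1]], src[[2]], src[[3]], drop = FALSE]
  b <- lev[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, ng, ng))
  counts <- tabulate((a[ok] - 1L) * ng + b[ok], nbins = ng * ng)
  m <- matrix(counts, ng, ng, byrow = TRUE)
  m + t(m)
}

# 25 co-occurrence features from a (symmetric) count matrix.
glcm_features_from_counts <- function(counts) {
  ng <- nrow(counts)
  n <- sum(counts)
  if (n == 0) stop("no valid voxel pair for GLCM")
  p <- counts / n
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  pi_marg <- rowSums(p)
  mu <- sum(i * p)
  sdm <- sqrt(sum((i - mu)^2 * p))
  # diagonal (difference) and cross-diagonal (sum) distributions
  dvals <- 0:(ng - 1)
  pd <- vapply(dvals, function(k) sum(p[abs(i - j) == k]), numeric(1))
  svals <- 2:(2 * ng)
  ps <- vapply(svals, function(k) sum(p[(i + j) == k]), numeric(1))
  diff_avg <- sum(dvals * pd)
  sum_avg <- sum(svals * ps)
  hxy <- -sum(xlog2x(p))
  hx <- -sum(xlog2x(pi_marg))
  pipj <- pi_marg[i] * pi_marg[j]
  hxy1 <- -sum(p * ifelse(pipj > 0, log2(pipj), 0))
  hxy2 <- -sum(xlog2x(pipj))
  degenerate <- sdm == 0  # single occupied gray level
  corr <- if (degenerate) 1 else (sum(i * j * p) - mu^2) / sdm^2
  ic1 <- if (degenerate || hx == 0) 1 else (hxy - hxy1) / hx
  ic2 <- if (degenerate) 1 else sqrt(1 - exp(-2 * max(hxy2 - hxy, 0)))
  c(joint_maximum = max(p),
    joint_average = mu,
    joint_variance = sum((i - mu)^2 * p),
    joint_entropy = hxy,
    difference_average = diff_avg,
    difference_variance = sum((dvals - diff_avg)^2 * pd),
    difference_entropy = -sum(xlog2x(pd)),
    sum_average = sum_avg,
    sum_variance = sum((svals - sum_avg)^2 * ps),
    sum_entropy = -sum(xlog2x(ps)),
    angular_second_moment = sum(p^2),
    contrast = sum((i - j)^2 * p),
    dissimilarity = sum(abs(i - j) * p),
    inverse_difference = sum(p / (1 + abs(i - j))),
    inverse_difference_normalised = sum(p / (1 + abs(i - j) / ng)),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    inverse_difference_moment_normalised = sum(p / (1 + ((i - j) / ng)^2)),
    inverse_variance = sum(p[i != j] / (i - j)[i != j]^2),
    correlation = corr,
    autocorrelation = sum(i * j * p),
    cluster_tendency = sum((i + j - 2 * mu)^2 * p),
    cluster_shade = sum((i + j - 2 * mu)^3 * p),
    cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    information_correlation_1 = ic1,
    information_correlation_2 = ic2)
}

#' Co-occurrence (GLCM) features
#'
#' Computes the 25 co-occurrence features over the 13 unique 3D directions at
#' Chebyshev distance 1. With `aggregation = "averaged"` the features are
#' computed per direction and averaged (directions without any valid pair are
#' skipped); with `"merged"` the 13 directional count matrices are summed,
#' normalized once, and the features computed from the pooled matrix.
#'
#' @param disc a `discretized_volume`.
#' @param aggregation `"averaged"` or `"merged"`.
#' @return Named numeric vector of 25 features (names prefixed
#'   `glcm_<aggregation>_`).
#' @export
glcm_features <- function(disc, aggregation = c("averaged", "merged")) {
  aggregation <- match.arg(aggregation)
  dirs <- directions_3d()
  mats <- lapply(seq_len(nrow(dirs)),
                 function(k) glcm_matrix(disc, dirs[k, ]))
  nonempty <- vapply(mats, function(m) sum(m) > 0, logical(1))
  if (!any(nonempty)) stop("no valid voxel pair in any direction")
  if (aggregation == "merged") {
    f <- glcm_features_from_counts(Reduce(`+`, mats))
  } else {
    per_dir <- vapply(mats[nonempty], glcm_features_from_counts,
                      numeric(length(.glcm_base)))
    f <- rowMeans(per_dir)
  }
  names(f) <- paste0("glcm_", aggregation, "_", .glcm_base)
  f
}
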