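# Intensity features: 18 statistics on raw HU values plus 7 features of the
# discretized gray-level histogram.

# Percentile rule pinned package-wide: linear interpolation between order
# statistics (stats::quantile type 7).
pctl <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

#' Intensity and histogram features
#'
#' The 18 statistics (mean, variance, skewness, excess kurtosis, median,
#' minimum, 10th/90th percentiles, maximum, interquartile range, range, mean
#' absolute deviation, robust mean absolute deviation, median absolute
#' deviation, coefficient of variation, quartile coefficient of dispersion,
#' energy, root mean square) are computed on the raw HU values of
#' non-missing voxels; variance and derived moments are population (divide
#' by n) quantities. The 7 histogram features (mean, variance, median,
#' range, entropy, uniformity, mode) are computed on the discretized gray
#' levels. Zero-variance regions yield skewness and kurtosis 0 and
#' coefficient of variation 0; the histogram mode breaks ties toward the
#' lowest level.
#'
#' @param mv a `masked_volume` (raw HU with NA marking missing voxels).
#' @param disc the matching `discretized_volume` from [discretize()].
#' @return Named numeric vector of 25 features.
#' @export
intensity_features <- function(mv, disc) {
  x <- mv$data[!is.na(mv$data)]
  if (length(x) == 0) stop("empty region")
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  s <- sqrt(v)
  skew <- if (s > 0) sum((x - mu)^3) / (n * s^3) else 0
  kurt <- if (s > 0) sum((x - mu)^4) / (n * v^2) - 3 else 0
  q <- pctl(x, c(0.10, 0.25, 0.50, 0.75, 0.90))
  inner <- x[x >= q[1] & x <= q[5]]
  rmad <- if (length(inner)) mean(abs(inner - mean(inner))) else 0
  qcd_den <- q[4] + q[2]
  lev <- disc$levels[!is.na(disc$levels)]
  tab <- tabulate(lev, disc$n_levels)
  ph <- tab / length(lev)
  mode_level <- which.max(tab)  # ties -> lowest level
  stats_out <- c(mu, v, skew, kurt, q[3], min(x), q[1], q[5], max(x),
                 q[4] - q[2], max(x) - min(x), mean(abs(x - mu)), rmad,
                 mean(abs(x - q[3])),
                 if (mu != 0) s / mu else 0,
                 if (qcd_den != 0) (q[4] - q[2]) / qcd_den else 0,
                 sum(x^2), sqrt(mean(x^2)))
  hist_out <- c(mean(lev), sum((lev - mean(lev))^2) / length(lev),
                stats::median(lev), max(lev) - min(lev),
                -sum(xlog2x(ph)), sum(ph^2), mode_level)
  out <- c(stats_out, hist_out)
  names(out) <- c(.stat_names, .hist_names)
  out
}

#' Extract the full 161-feature vector for a region
#'
#' Runs the complete feature battery (25 intensity + 136 texture features)
#' on a masked region. Regions smaller than `min_voxels` non-missing voxels
#' (default 27) are excluded from analysis and signal an error of class
#' `region_too_small`.
#'
#' @param mv a `masked_volume`.
#' @param bin_width discretization bin width in HU (default 5).
#' @param min_voxels minimum region size in voxels (default 27).
#' @return Named numeric vector of length 161 in [feature_names()] order.
#' @examples
#' vol <- image_volume(array(stats::rnorm(125, 80, 15), c(5, 5, 5)))
#' roi <- roi_mask(array(TRUE, c(5, 5, 5)))
#' mv <- apply_hu_window(vol, roi)
#' fv <- extract_feature_vector(mv)
#' length(fv)  # 161
#' @export
extract_feature_vector <- function(mv, bin_width = 5, min_voxels = 27) {
  if (!inherits(mv, "masked_volume")) stop("'mv' must be a masked_volume")
  if (mv$roi_voxel_count < min_voxels) {
    cnd <- simpleError(sprintf(
      "region excluded: %d voxels < minimum %d", mv$roi_voxel_count,
      min_voxels))
    class(cnd) <- c("region_too_small", class(cnd))
    stop(cnd)
  }
  cropped <- mv
  cropped$data <- crop_to_roi(mv$data)
  disc <- discretize(cropped, bin_width)
  out <- c(intensity_features(cropped, disc),
           glcm_features(disc, "averaged"), glcm_features(disc, "merged"),
           glrlm_features(disc, "averaged"), glrlm_features(disc, "merged"),
           zone_features(disc),
           neighbourhood_features(disc))
  stopifnot(identical(names(out), feature_names()))
  out
}
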