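#' Resample a volume to an isotropic grid
#'
#' Resamples to cubic voxels of edge `target` mm. Images use trilinear
#' interpolation; masks use nearest-neighbor (set `method = "nearest"`).
#' The output grid is corner-aligned with the input (same origin) and covers
#' the input's physical extent: the output has `ceiling(n * s / target)`
#' voxels along an axis with `n` input voxels of spacing `s`. Sample points
#' outside the input voxel-center range are clamped to the nearest edge.
#'
#' @param vol an [image_volume()].
#' @param target isotropic voxel edge in mm (default 3.3, a typical largest
#'   slice thickness in planning CT).
#' @param method `"trilinear"` (default) or `"nearest"`.
#' @return A resampled [image_volume()] with spacing `c(target, target,
#'   target)`.
#' @export
resample_isotropic <- function(vol, target = 3.3,
                               method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (!inherits(vol, "image_volume")) stop("'vol' must be an image_volume")
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target) ||
      target <= 0)
    stop("'target' must be a single positive number (mm)")
  d_in <- dim(vol$data)
  s_in <- vol$spacing
  d_out <- pmax(1L, as.integer(ceiling(d_in * s_in / target - 1e-9)))
  # continuous input index (1-based) of each output voxel center, per axis
  idx <- lapply(1:3, function(ax) {
    x <- ((seq_len(d_out[ax]) - 1) * target) / s_in[ax] + 1
    pmin(pmax(x, 1), d_in[ax])
  })
  if (method == "nearest") {
    ii <- lapply(idx, function(x) as.integer(floor(x + 0.5)))
    out <- vol$data[as.matrix(expand.grid(ii[[1]], ii[[2]], ii[[3]]))]
    dim(out) <- d_out
  } else {
    lo <- lapply(1:3, function(ax) pmax(pmin(floor(idx[[ax]]), d_in[ax] - 1), 1))
    hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1, d_in[ax]))
    fr <- lapply(1:3, function(ax) idx[[ax]] - lo[[ax]])
    out <- array(0, d_out)
    g <- expand.grid(x = seq_len(d_out[1]), y = seq_len(d_out[2]),
                     z = seq_len(d_out[3]))
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- (if (cx) fr[[1]][g$x] else 1 - fr[[1]][g$x]) *
           (if (cy) fr[[2]][g$y] else 1 - fr[[2]][g$y]) *
           (if (cz) fr[[3]][g$z] else 1 - fr[[3]][g$z])
      corner <- cbind(if (cx) hi[[1]][g$x] else lo[[1]][g$x],
                      if (cy) hi[[2]][g$y] else lo[[2]][g$y],
                      if (cz) hi[[3]][g$z] else lo[[3]][g$z])
      out <- out + array(w * vol$data[corner], d_out)
    }
  }
  image_volume(out, spacing = rep(target, 3), origin = vol$origin)
}

#' Resample an ROI mask to an isotropic grid (nearest-neighbor)
#'
#' @param mask an [roi_mask()].
#' @param target isotropic voxel edge in mm.
#' @return A resampled [roi_mask()].
#' @export
resample_mask <- function(mask, target = 3.3) {
  v <- image_volume(array(as.numeric(mask$data), dim(mask$data)),
                    mask$spacing, mask$origin)
  r <- resample_isotropic(v, target, method = "nearest")
  roi_mask(r$data, r$spacing, r$origin)
}

#' Restrict a volume to an ROI and a Hounsfield-unit window
#'
#' Voxels outside the ROI, or with values outside the closed interval
#' `[low, high]`, are set to `NA`. The default window of -20 to 180 HU limits
#' the analysis to soft tissue; both bounds are inclusive.
#'
#' @param vol an [image_volume()] in HU.
#' @param roi an [roi_mask()] on the same grid.
#' @param low,high window bounds in HU (defaults -20 and 180).
#' @return A `masked_volume`: list with `data` (NA-marked array), `spacing`,
#'   `origin`, `window`, and `roi_voxel_count` (number of non-missing
#'   voxels).
#' @export
apply_hu_window <- function(vol, roi, low = -20, high = 180) {
  if (low >= high) stop("'low' must be < 'high'")
  check_same_grid(vol, roi)
  data <- vol$data
  keep <- roi$data & !is.na(data) & data >= low & data <= high
  data[!keep] <- NA_real_
  structure(list(data = data, spacing = vol$spacing, origin = vol$origin,
                 window = c(low, high), roi_voxel_count = sum(keep)),
            class = "masked_volume")
}

#' @export
print.masked_volume <- function(x, ...) {
  cat(sprintf("masked_volume: %s voxels, %d in ROI, window [%g, %g] HU\n",
              paste(dim(x$data), collapse = "x"), x$roi_voxel_count,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Clear mask foreground on artifact-affected slices
#'
#' Removes contoured voxels on axial (z) slices affected by e.g. metal
#' artifacts. Slice indices are 1-based and user-supplied; artifact detection
#' itself is out of scope.
#'
#' @param mask an [roi_mask()].
#' @param slice_indices integer z indices to clear (may be empty).
#' @return The mask with the listed slices emptied.
#' @export
remove_artifact_slices <- function(mask, slice_indices) {
  slice_indices <- as.integer(slice_indices)
  nz <- dim(mask$data)[3]
  if (length(slice_indices) &&
      (any(slice_indices < 1L) || any(slice_indices > nz)))
    stop(sprintf("slice index out of range 1..%d", nz))
  if (length(slice_indices)) mask$data[, , slice_indices] <- FALSE
  mask
}

#' Segment a volume by a relative intensity threshold
#'
#' Selects voxels with value at least `fraction` times the volume maximum;
#' with the default 0.4 this is the common 40%-of-maximum rule used to
#' delineate high-uptake sub-volumes on PET.
#'
#' @param vol an [image_volume()]; its maximum must be positive.
#' @param fraction relative threshold in (0, 1]; default 0.4.
#' @return An [roi_mask()] of voxels `>= fraction * max(vol)`.
#' @export
segment_relative_threshold <- function(vol, fraction = 0.4) {
  mx <- max(vol$data, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("volume maximum must be positive")
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  sel <- !is.na(vol$data) & vol$data >= fraction * mx
  roi_mask(sel, vol$spacing, vol$origin)
}

#' Split a tumor mask into recurrent and control regions
#'
#' `gtv_rec` is the intersection of the primary tumor (GTV) with the
#' recurrence mask; `gtv_control` is the GTV minus the recurrence. The two
#' are disjoint and partition the GTV.
#'
#' @param gtv,rec [roi_mask()] objects on the same grid.
#' @return List with `rec` and `control` masks.
#' @export
derive_region_pair <- function(gtv, rec) {
  check_same_grid(gtv, rec)
  list(rec = roi_mask(gtv$data & rec$data, gtv$spacing, gtv$origin),
       control = roi_mask(gtv$data & !rec$data, gtv$spacing, gtv$origin))
}

#' Minimum-volume acceptance check
#'
#' Regions with fewer than `minimum` analyzable voxels are excluded from
#' radiomics analysis (default 27, i.e. a 3x3x3 neighborhood).
#'
#' @param region a `masked_volume` or [roi_mask()].
#' @param minimum minimum voxel count (default 27).
#' @return `TRUE` if the region has at least `minimum` non-missing/foreground
#'   voxels.
#' @export
check_min_volume <- function(region, minimum = 27) {
  n <- if (inherits(region, "masked_volume")) region$roi_voxel_count
       else if (inherits(region, "roi_mask")) sum(region$data)
       else sum(!is.na(region))
  n >= minimum
}
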