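# Sub-volume partitioning of a GTV mask: fixed-count octants around the
# tumor center, and a fixed-size shifted grid with optimized placement.

#' Center of a tumor mask
#'
#' Rounded (half-up) center of mass of the foreground voxels, in 1-based
#' voxel coordinates.
#'
#' @param mask an [roi_mask()]; must be non-empty.
#' @return Integer length-3 voxel coordinate.
#' @export
gtv_center <- function(mask) {
  w <- which(mask$data, arr.ind = TRUE)
  if (nrow(w) == 0) stop("empty mask")
  as.integer(floor(colMeans(w) + 0.5))
}

new_partition <- function(scheme, subregions, params, grid_dim, spacing,
                          origin) {
  structure(list(scheme = scheme, subregions = subregions, params = params,
                 grid_dim = grid_dim, spacing = spacing, origin = origin),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  ns <- length(x$subregions)
  counts <- vapply(x$subregions, function(s) s$roi_voxel_count, numeric(1))
  labs <- vapply(x$subregions, function(s) s$label %||% "unlabeled",
                 character(1))
  cat(sprintf("partition (%s): %d sub-regions, %d retained, %d recurrent\n",
              x$scheme, ns, sum(counts > 0 & !vapply(x$subregions,
                function(s) isTRUE(s$excluded), logical(1))),
              sum(labs == "recurrent")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition a GTV into 8 octants (fixed sub-region count)
#'
#' Three axis-aligned cutting planes through [gtv_center()] split the mask
#' foreground into 8 octants whose volume depends on the GTV size. A voxel
#' whose index equals the center coordinate on an axis goes to the upper
#' half. Empty octants are kept in the partition, flagged `excluded`, and
#' skipped at feature extraction.
#'
#' @param mask an [roi_mask()]; must be non-empty.
#' @param k number of sub-regions; only the default 8 (2 per axis) is
#'   supported.
#' @return A `partition` with 8 sub-regions, each holding the linear voxel
#'   indices of its ROI voxels.
#' @export
partition_fixed_count <- function(mask, k = 8) {
  if (k != 8) stop("only k = 8 (octants) is supported")
  ctr <- gtv_center(mask)
  w <- which(mask$data, arr.ind = TRUE)
  lin <- which(mask$data)
  oct <- 1L + (w[, 1] >= ctr[1]) + 2L * (w[, 2] >= ctr[2]) +
    4L * (w[, 3] >= ctr[3])
  subs <- lapply(1:8, function(i) {
    vox <- lin[oct == i]
    list(id = i, voxels = vox, roi_voxel_count = length(vox),
         label = NULL, overlap_fraction = NA_real_,
         excluded = length(vox) == 0)
  })
  new_partition("fixed_count", subs, list(k = 8, center = ctr),
                dim(mask$data), mask$spacing, mask$origin)
}

#' Partition a GTV into fixed-size grid cells with optimized placement
#'
#' A non-overlapping `g`\eqn{^3} grid tiles the mask bounding box. The grid
#' offset is searched over all `shift`\eqn{^3} placements and chosen to
#' cover as much of the GTV as possible: the placement maximizing the total
#' ROI volume inside retained cells (cells with at least `min_cell_voxels`
#' ROI voxels), with ties broken toward fewer (hence larger) retained cells
#' — texture is better estimated on larger cells — and then by the
#' lexicographically smallest offset. Cells below the threshold are
#' discarded; retained cells become sub-regions.
#'
#' @param mask an [roi_mask()]; must be non-empty.
#' @param g cell edge in voxels (default 5).
#' @param shift offset search range per axis (default 5; candidates
#'   `0..shift-1`).
#' @param min_cell_voxels retention threshold T (default 25 ROI voxels).
#' @return A `partition` whose sub-regions are the retained cells; the
#'   chosen offset is stored in `params$offset`.
#' @export
partition_fixed_size <- function(mask, g = 5, shift = 5,
                                 min_cell_voxels = 25) {
  w <- which(mask$data, arr.ind = TRUE)
  if (nrow(w) == 0) stop("empty mask")
  lin <- which(mask$data)
  bbmin <- apply(w, 2, min)
  best <- NULL
  for (oz in 0:(shift - 1)) for (oy in 0:(shift - 1)) for (ox in 0:(shift - 1)) {
    off <- c(ox, oy, oz)
    # cell coordinate per foreground voxel; grid anchored at bbmin - offset
    cc <- floor(sweep(sweep(w, 2, bbmin), 2, off, `+`) / g)
    key <- cc[, 1] + 1000L * cc[, 2] + 1000000L * cc[, 3]
    counts <- table(key)
    retained <- counts >= min_cell_voxels
    score <- c(sum(counts[retained]), -sum(retained))
    if (is.null(best) || score[1] > best$score[1] ||
        (score[1] == best$score[1] && score[2] > best$score[2])) {
      best <- list(score = score, off = off, key = key,
                   keep = names(counts)[retained])
    }
  }
  if (length(best$keep) == 0)
    stop(sprintf("no grid cell reaches %d ROI voxels", min_cell_voxels))
  subs <- lapply(seq_along(best$keep), function(i) {
    vox <- lin[best$key == as.integer(best$keep[i])]
    list(id = i, voxels = vox, roi_voxel_count = length(vox),
         label = NULL, overlap_fraction = NA_real_, excluded = FALSE)
  })
  new_partition("fixed_size", subs,
                list(g = g, shift = shift, min_cell_voxels = min_cell_voxels,
                     offset = best$off, n_candidates = shift^3),
                dim(mask$data), mask$spacing, mask$origin)
}

#' Label sub-regions from a recurrence mask
#'
#' A sub-region is labeled `recurrent` when strictly more than
#' `threshold` (default 50%) of its ROI voxels lie inside the recurrent
#' region `gtv_rec`; all other sub-regions are `control`.
#'
#' @param partition a `partition`.
#' @param gtvrec an [roi_mask()] of the recurrent region, on the same grid.
#' @param threshold overlap fraction above which a sub-region is recurrent
#'   (strict inequality; default 0.5).
#' @return The partition with `label` and `overlap_fraction` filled in.
#' @export
label_subregions <- function(partition, gtvrec, threshold = 0.5) {
  if (!identical(partition$grid_dim, dim(gtvrec$data)))
    stop("grid mismatch between partition and recurrence mask")
  rec <- gtvrec$data
  partition$subregions <- lapply(partition$subregions, function(s) {
    if (s$roi_voxel_count > 0) {
      s$overlap_fraction <- sum(rec[s$voxels]) / s$roi_voxel_count
      s$label <- if (s$overlap_fraction > threshold) "recurrent" else "control"
    }
    s
  })
  partition
}

#' Feature table of a partitioned region
#'
#' One row per retained sub-region with its 161 features. The sub-region's
#' feature extraction sees only its own ROI voxels (all others are missing).
#' Sub-regions whose non-missing voxel count falls below `min_voxels` are
#' dropped, with the reason recorded in `attr(, "dropped")`.
#'
#' @param mv the analysis-ready `masked_volume` on the partition's grid.
#' @param partition a labeled `partition`.
#' @param patient_id identifier copied into every row.
#' @param bin_width discretization bin width in HU.
#' @param min_voxels global minimum region size (default 27).
#' @return data.frame with columns `patient_id`, `region_id`, `label`,
#'   `roi_voxel_count`, `overlap_fraction`, and the 161 features.
#' @export
build_feature_table <- function(mv, partition, patient_id = "p1",
                                bin_width = 5, min_voxels = 27) {
  stopifnot(identical(dim(mv$data), partition$grid_dim))
  rows <- list()
  dropped <- list()
  for (s in partition$subregions) {
    if (isTRUE(s$excluded) || s$roi_voxel_count == 0) {
      dropped[[length(dropped) + 1]] <-
        list(region_id = s$id, reason = "empty sub-region")
      next
    }
    sub <- mv
    keep <- array(FALSE, dim(mv$data))
    keep[s$voxels] <- TRUE
    sub$data[!keep] <- NA_real_
    sub$roi_voxel_count <- sum(!is.na(sub$data))
    if (sub$roi_voxel_count < min_voxels) {
      dropped[[length(dropped) + 1]] <-
        list(region_id = s$id,
             reason = sprintf("%d voxels < minimum %d",
                              sub$roi_voxel_count, min_voxels))
      next
    }
    fv <- extract_feature_vector(sub, bin_width = bin_width,
                                 min_voxels = min_voxels)
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = patient_id, region_id = s$id,
      label = s$label %||% "unlabeled",
      roi_voxel_count = sub$roi_voxel_count,
      overlap_fraction = s$overlap_fraction,
      as.list(fv), check.names = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0))
  attr(out, "dropped") <- dropped
  out
}

#' Export a per-sub-region parametric map
#'
#' Builds a volume in which every ROI voxel of a retained sub-region carries
#' that sub-region's scalar value (e.g. a radiomic feature or a predicted
#' recurrence probability); all other voxels are missing. Such maps
#' visualize heterogeneity or predicted radioresistance across the GTV.
#'
#' @param partition a `partition`.
#' @param values numeric vector, one value per retained (non-excluded)
#'   sub-region, in sub-region order.
#' @return An [image_volume()] with NA outside the mapped sub-regions.
#' @export
export_parametric_map <- function(partition, values) {
  keep <- !vapply(partition$subregions, function(s)
    isTRUE(s$excluded) || s$roi_voxel_count == 0, logical(1))
  subs <- partition$subregions[keep]
  if (length(values) != length(subs))
    stop(sprintf("%d values for %d retained sub-regions", length(values),
                 length(subs)))
  out <- array(NA_real_, partition$grid_dim)
  for (i in seq_along(subs)) out[subs[[i]]$voxels] <- values[i]
  image_volume(out, partition$spacing, partition$origin)
}
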