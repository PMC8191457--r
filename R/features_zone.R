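# Zone (GLSZM) and distance-zone (GLDZM) features.

#' Enumerate gray-level zones
#'
#' Zones are 26-connected components of equal gray level among non-missing
#' voxels. Each zone's distance is the minimum over its voxels of the
#' Chebyshev distance to the ROI border, where missing voxels and the volume
#' edge count as border and border-adjacent voxels have distance 1.
#'
#' @param disc a `discretized_volume`.
#' @return data.frame with one row per zone: `level`, `size`, `distance`.
#' @export
gl_zones <- function(disc) {
  lev <- disc$levels
  if (!any(!is.na(lev))) stop("empty region")
  p <- pad_na(lev)
  dp <- dim(p)
  offs <- linear_offsets(offsets_26(), dp)
  core <- which(!is.na(p))
  # Chebyshev distance-to-border map by layered 26-dilation from the border.
  dist <- rep(NA_integer_, length(p))
  neigh <- rep(core, each = length(offs)) + offs
  border_adjacent <- core[colSums(matrix(is.na(p[neigh]),
                                         nrow = length(offs))) > 0]
  dist[border_adjacent] <- 1L
  frontier <- border_adjacent
  layer <- 1L
  while (length(frontier)) {
    nb <- unique(rep(frontier, each = length(offs)) + offs)
    nb <- nb[!is.na(p[nb]) & is.na(dist[nb])]
    layer <- layer + 1L
    dist[nb] <- layer
    frontier <- nb
  }
  # Flood fill equal-level 26-connected components.
  zone_id <- rep(NA_integer_, length(p))
  zones_level <- integer(0); zones_size <- integer(0); zones_dist <- integer(0)
  nz <- 0L
  for (v in core) {
    if (!is.na(zone_id[v])) next
    nz <- nz + 1L
    lv <- p[v]
    stack <- v
    zone_id[v] <- nz
    size <- 0L
    dmin <- .Machine$integer.max
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      if (dist[cur] < dmin) dmin <- dist[cur]
      nb <- cur + offs
      nb <- nb[!is.na(p[nb]) & p[nb] == lv & is.na(zone_id[nb])]
      zone_id[nb] <- nz
      stack <- c(stack, nb)
    }
    zones_level <- c(zones_level, lv)
    zones_size <- c(zones_size, size)
    zones_dist <- c(zones_dist, dmin)
  }
  data.frame(level = zones_level, size = zones_size, distance = zones_dist)
}

# Generic size/distance-zone feature computation: `attr_vals` is the zone
# size (GLSZM) or zone distance (GLDZM).
zone_family_features <- function(zones, attr_vals, ng, nv, names_out) {
  ns <- nrow(zones)
  m <- as.matrix(table(factor(zones$level, levels = seq_len(ng)),
                       factor(attr_vals, levels = seq_len(max(attr_vals)))))
  p <- m / ns
  i <- matrix(seq_len(ng), nrow(m), ncol(m))
  a <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  si <- rowSums(m)
  sa <- colSums(m)
  mu_i <- sum(i * p)
  mu_a <- sum(a * p)
  vals <- c(sum(p / a^2), sum(p * a^2),
            sum(p / i^2), sum(p * i^2),
            sum(p / (i^2 * a^2)), sum(p * i^2 / a^2),
            sum(p * a^2 / i^2), sum(p * i^2 * a^2),
            sum(si^2) / ns, sum(si^2) / ns^2,
            sum(sa^2) / ns, sum(sa^2) / ns^2,
            ns / nv,
            sum((i - mu_i)^2 * p), sum((a - mu_a)^2 * p),
            -sum(xlog2x(p)))
  names(vals) <- names_out
  vals
}

#' Zone-based (GLSZM and GLDZM) features
#'
#' 16 size-zone features (zone attribute = zone size in voxels) and 16
#' distance-zone features (zone attribute = zone distance to the ROI
#' border).
#'
#' @param disc a `discretized_volume`.
#' @return Named numeric vector of 32 features.
#' @export
zone_features <- function(disc) {
  zones <- gl_zones(disc)
  nv <- sum(!is.na(disc$levels))
  c(zone_family_features(zones, zones$size, disc$n_levels, nv, .glszm_names),
    zone_family_features(zones, zones$distance, disc$n_levels, nv,
                         .gldzm_names))
}
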