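# Neighbourhood gray-tone difference (NGTDM) and neighbouring gray-level
# dependence (NGLDM) features; 26-neighbourhood, Chebyshev distance 1.

# Per-voxel neighbour statistics: count of non-missing neighbours, their
# level sum, and the count of neighbours with the same level (NGLDM, alpha=0).
neighbour_stats <- function(disc) {
  lev <- disc$levels
  p <- pad_na(lev)
  offs <- linear_offsets(offsets_26(), dim(p))
  core <- which(!is.na(p))
  nb <- rep(core, each = length(offs)) + offs
  nbl <- matrix(p[nb], nrow = length(offs))
  cl <- p[core]
  list(core = core,
       level = cl,
       n_neigh = colSums(!is.na(nbl)),
       sum_neigh = colSums(nbl, na.rm = TRUE),
       n_same = colSums(sweep(nbl, 2, cl, `==`), na.rm = TRUE))
}

#' Neighbourhood gray-tone difference (NGTDM) features
#'
#' Coarseness, contrast, busyness, complexity, strength; computed over
#' non-missing voxels that have at least one non-missing 26-neighbour, with
#' neighbour averages taken over non-missing neighbours only.
#'
#' @param disc a `discretized_volume`.
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(disc) {
  st <- neighbour_stats(disc)
  valid <- st$n_neigh > 0
  if (!any(valid)) stop("no voxel with a non-missing neighbor")
  lv <- st$level[valid]
  abar <- st$sum_neigh[valid] / st$n_neigh[valid]
  nv <- sum(valid)
  ng <- disc$n_levels
  n_i <- tabulate(lv, ng)
  s_i <- vapply(seq_len(ng), function(g) sum(abs(g - abar)[lv == g]),
                numeric(1))
  p_i <- n_i / nv
  occ <- which(p_i > 0)
  ngp <- length(occ)
  ii <- matrix(occ, ngp, ngp)
  jj <- t(ii)
  pi_ <- p_i[occ]
  pm <- matrix(pi_, ngp, ngp)
  pn <- t(pm)
  coarse_den <- sum(p_i * s_i)
  contrast <- if (ngp > 1)
    sum(pm * pn * (ii - jj)^2) / (ngp * (ngp - 1)) * sum(s_i) / nv else 0
  busy_den <- sum(abs(ii * pm - jj * pn))
  complexity <- if (nv > 0)
    sum(abs(ii - jj) * (pm * s_i[occ][row(pm)] + pn * s_i[occ][col(pn)]) /
          (pm + pn)) / nv else 0
  strength <- if (sum(s_i) > 0)
    sum((pm + pn) * (ii - jj)^2) / sum(s_i) else 0
  c(ngtdm_coarseness = if (coarse_den > 0) 1 / coarse_den else 1e6,
    ngtdm_contrast = contrast,
    ngtdm_busyness = if (busy_den > 0) coarse_den / busy_den else 0,
    ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

#' Neighbouring gray-level dependence (NGLDM) features
#'
#' Dependence count of a voxel = number of 26-neighbours with the same gray
#' level (coarseness parameter alpha = 0); missing neighbours never count.
#' The dependence-count axis of the matrix is `k + 1` (so a voxel with no
#' dependent neighbour sits in column 1), which keeps the low-dependence
#' emphasis weights finite.
#'
#' @param disc a `discretized_volume`.
#' @return Named numeric vector of 17 features.
#' @export
ngldm_features <- function(disc) {
  st <- neighbour_stats(disc)
  valid <- st$n_neigh > 0
  if (!any(valid)) stop("no voxel with a non-missing neighbor")
  lv <- st$level[valid]
  k <- st$n_same[valid] + 1L  # dependence-count column index
  ng <- disc$n_levels
  ns <- length(lv)
  nv <- sum(!is.na(disc$levels))
  m <- as.matrix(table(factor(lv, levels = seq_len(ng)),
                       factor(k, levels = seq_len(max(k)))))
  p <- m / ns
  i <- matrix(seq_len(ng), nrow(m), ncol(m))
  j <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  si <- rowSums(m)
  sj <- colSums(m)
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  c(ngldm_low_dependence_emphasis = sum(p / j^2),
    ngldm_high_dependence_emphasis = sum(p * j^2),
    ngldm_low_gray_level_count_emphasis = sum(p / i^2),
    ngldm_high_gray_level_count_emphasis = sum(p * i^2),
    ngldm_low_dependence_low_gray_level_emphasis = sum(p / (i^2 * j^2)),
    ngldm_low_dependence_high_gray_level_emphasis = sum(p * i^2 / j^2),
    ngldm_high_dependence_low_gray_level_emphasis = sum(p * j^2 / i^2),
    ngldm_high_dependence_high_gray_level_emphasis = sum(p * i^2 * j^2),
    ngldm_gray_level_nonuniformity = sum(si^2) / ns,
    ngldm_gray_level_nonuniformity_normalised = sum(si^2) / ns^2,
    ngldm_dependence_count_nonuniformity = sum(sj^2) / ns,
    ngldm_dependence_count_nonuniformity_normalised = sum(sj^2) / ns^2,
    ngldm_dependence_count_percentage = ns / nv,
    ngldm_gray_level_variance = sum((i - mu_i)^2 * p),
    ngldm_dependence_count_variance = sum((j - mu_j)^2 * p),
    ngldm_dependence_count_entropy = -sum(xlog2x(p)),
    ngldm_dependence_count_energy = sum(p^2))
}

#' Combined neighbourhood features (NGTDM + NGLDM)
#'
#' @param disc a `discretized_volume`.
#' @return Named numeric vector of 22 features.
#' @export
neighbourhood_features <- function(disc) {
  c(ngtdm_features(disc), ngldm_features(disc))
}
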