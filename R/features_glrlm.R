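#' Run enumeration for one direction
#'
#' A run is a maximal sequence of consecutive voxels along the direction
#' with the same gray level; a missing voxel (or the volume edge) breaks the
#' run.
#'
#' @param disc a `discretized_volume`.
#' @param direction integer length-3 offset.
#' @return data.frame with columns `level` and `length`, one row per run.
#' @export
glrlm_runs <- function(disc, direction) {
  lev <- disc$levels
  d <- dim(lev)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  # steps back to the line start, then the start voxel itself as line id
  back <- rep(Inf, nrow(idx))
  for (ax in 1:3) {
    if (direction[ax] == 1) back <- pmin(back, idx[, ax] - 1)
    if (direction[ax] == -1) back <- pmin(back, d[ax] - idx[, ax])
  }
  start <- idx - back * rep(direction, each = nrow(idx))
  linekey <- start[, 1] + (start[, 2] - 1) * d[1] +
    (start[, 3] - 1) * d[1] * d[2]
  ord <- order(linekey, back)
  lv <- as.vector(lev)[ord]
  lk <- linekey[ord]
  n <- length(lv)
  if (n == 0) return(data.frame(level = integer(0), length = integer(0)))
  brk <- c(TRUE,
           lk[-1] != lk[-n] | is.na(lv[-1]) | is.na(lv[-n]) |
             (lv[-1] != lv[-n]) %in% TRUE)
  runid <- cumsum(brk)
  len <- tabulate(runid)
  level <- lv[brk]
  keep <- !is.na(level)
  data.frame(level = level[keep], length = len[keep])
}

# 16 run-length features from a run table (level, length) and the number of
# analyzable voxels per direction (nv); ndir = number of pooled directions.
glrlm_features_from_runs <- function(runs, ng, nv, ndir = 1) {
  if (nrow(runs) == 0) stop("no runs (empty region)")
  nr <- nrow(runs)
  # r[i, l]: number of runs of level i and length l
  r <- as.matrix(table(factor(runs$level, levels = seq_len(ng)),
                       factor(runs$length, levels = seq_len(max(runs$length)))))
  p <- r / nr
  i <- matrix(seq_len(ng), nrow(r), ncol(r))
  l <- matrix(seq_len(ncol(r)), nrow(r), ncol(r), byrow = TRUE)
  ri <- rowSums(r)   # runs per level
  rl <- colSums(r)   # runs per length
  mu_i <- sum(i * p)
  mu_l <- sum(l * p)
  c(short_runs_emphasis = sum(p / l^2),
    long_runs_emphasis = sum(p * l^2),
    low_gray_level_run_emphasis = sum(p / i^2),
    high_gray_level_run_emphasis = sum(p * i^2),
    short_run_low_gray_level_emphasis = sum(p / (i^2 * l^2)),
    short_run_high_gray_level_emphasis = sum(p * i^2 / l^2),
    long_run_low_gray_level_emphasis = sum(p * l^2 / i^2),
    long_run_high_gray_level_emphasis = sum(p * i^2 * l^2),
    gray_level_nonuniformity = sum(ri^2) / nr,
    gray_level_nonuniformity_normalised = sum(ri^2) / nr^2,
    run_length_nonuniformity = sum(rl^2) / nr,
    run_length_nonuniformity_normalised = sum(rl^2) / nr^2,
    run_percentage = nr / (nv * ndir),
    gray_level_variance = sum((i - mu_i)^2 * p),
    run_length_variance = sum((l - mu_l)^2 * p),
    run_entropy = -sum(xlog2x(p)))
}

#' Run-length (GLRLM) features
#'
#' Computes the 16 run-length features over the 13 unique 3D directions.
#' `"averaged"` computes features per direction and averages them;
#' `"merged"` pools the runs of all 13 directions into one matrix before
#' computing features (run percentage is then normalized by 13 times the
#' voxel count).
#'
#' @param disc a `discretized_volume`.
#' @param aggregation `"averaged"` or `"merged"`.
#' @return Named numeric vector of 16 features (names prefixed
#'   `glrlm_<aggregation>_`).
#' @export
glrlm_features <- function(disc, aggregation = c("averaged", "merged")) {
  aggregation <- match.arg(aggregation)
  dirs <- directions_3d()
  nv <- sum(!is.na(disc$levels))
  if (nv == 0) stop("empty region")
  runs <- lapply(seq_len(nrow(dirs)), function(k) glrlm_runs(disc, dirs[k, ]))
  if (aggregation == "merged") {
    f <- glrlm_features_from_runs(do.call(rbind, runs), disc$n_levels, nv,
                                  ndir = nrow(dirs))
  } else {
    per_dir <- vapply(runs, glrlm_features_from_runs,
                      numeric(length(.glrlm_base)),
                      ng = disc$n_levels, nv = nv)
    f <- rowMeans(per_dir)
  }
  names(f) <- paste0("glrlm_", aggregation, "_", .glrlm_base)
  f
}
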