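# Synthetic CT phantoms: ellipsoidal tumors with spatially correlated
# texture and an embedded, more heterogeneous recurrent sub-volume.

#' Specification of a single synthetic phantom
#'
#' The phantom emulates a contrast-enhanced planning CT of a soft-tissue
#' tumor: an ellipsoidal GTV with smooth (spatially correlated Gaussian)
#' HU texture sits in a distinct background. The recurrent sub-volume is a
#' cap of the ellipsoid (the GTV on one side of a plane cut, oriented along
#' `rec_direction` and placed so the cap holds `rec_fraction` of the GTV
#' volume), so recurrent and control regions are geometrically comparable
#' pieces of the same body and differ by texture, not shape. Heterogeneity
#' is additive: inside the cap an independent short-range field is added on
#' top of the shared tumor texture, scaled so the voxel-value SD is
#' `effect_size` times the control SD. At `effect_size = 1` the excess
#' vanishes and the phantom is a homogeneous tumor with an arbitrarily
#' labeled sub-volume — an exact null with no texture seam. HU levels are
#' chosen so the default -20..180 HU analysis window retains essentially
#' all GTV voxels.
#'
#' @param shape volume dimensions in voxels (default 64 x 64 x 28).
#' @param spacing voxel spacing in mm (default 1 x 1 x 3, a typical planning
#'   CT grid).
#' @param gtv_semiaxes GTV ellipsoid semi-axes in mm (default 20, 18, 16).
#' @param rec_fraction recurrent fraction of the GTV volume (default 0.2,
#'   the cohort average reported for head-and-neck recurrences).
#' @param rec_direction outward normal of the cap cut plane (default x);
#'   normalized internally.
#' @param gtv_mean mean GTV attenuation in HU (default 90, enhancing soft
#'   tissue).
#' @param control_sd texture SD of the controlled tumor in HU (default 15).
#' @param control_corr correlation length (Gaussian kernel SD) of the
#'   controlled texture in mm (default 4).
#' @param effect_size recurrent/control noise-SD ratio (>= 1; default 2).
#' @param rec_corr correlation length of the added heterogeneity field in mm
#'   (default 2; shorter than `control_corr` = busier texture).
#' @param background_mean,background_sd background HU (defaults 0 and 12).
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 28), spacing = c(1, 1, 3),
                         gtv_semiaxes = c(20, 18, 16), rec_fraction = 0.2,
                         rec_direction = c(1, 0, 0), gtv_mean = 90,
                         control_sd = 15, control_corr = 4,
                         effect_size = 2, rec_corr = 2,
                         background_mean = 0, background_sd = 12,
                         seed = 1) {
  if (rec_fraction <= 0 || rec_fraction >= 1)
    stop("'rec_fraction' must be in (0, 1)")
  if (effect_size < 1) stop("'effect_size' must be >= 1")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 gtv_semiaxes = as.numeric(gtv_semiaxes),
                 rec_fraction = rec_fraction,
                 rec_direction = as.numeric(rec_direction),
                 gtv_mean = gtv_mean, control_sd = control_sd,
                 control_corr = control_corr, effect_size = effect_size,
                 rec_corr = rec_corr, background_mean = background_mean,
                 background_sd = background_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Separable Gaussian smoothing; sigma in voxels per axis.
gauss_smooth <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    n <- d[ax]
    # band matrix applying the truncated kernel with edge renormalization
    km <- matrix(0, n, n)
    for (o in -r:r) {
      idx <- seq_len(n)
      j <- idx + o
      ok <- j >= 1 & j <= n
      km[cbind(idx[ok], j[ok])] <- k[o + r + 1]
    }
    km <- km / rowSums(km)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    ap <- km %*% matrix(ap, nrow = dp[1])
    dim(ap) <- dp
    a <- aperm(ap, order(perm))
  }
  a
}

# Correlated Gaussian field with (empirical) unit SD.
correlated_field <- function(shape, spacing, corr_mm) {
  f <- gauss_smooth(array(stats::rnorm(prod(shape)), shape),
                    corr_mm / spacing)
  f / stats::sd(f)
}

#' Generate a synthetic phantom
#'
#' @param spec a [phantom_spec()].
#' @return List with `vol` ([image_volume()]), `gtv` and `rec`
#'   ([roi_mask()] objects). The recurrence mask is contained in the GTV
#'   mask by construction.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)
  d <- spec$shape
  sp <- spec$spacing
  ctr_mm <- (d - 1) / 2 * sp
  ax <- spec$gtv_semiaxes
  # normalized ellipsoid coordinates of every voxel center
  xs <- lapply(1:3, function(a) ((seq_len(d[a]) - 1) * sp[a] - ctr_mm[a]) /
                 ax[a])
  g <- expand.grid(x = xs[[1]], y = xs[[2]], z = xs[[3]])
  rad2 <- array(g$x^2 + g$y^2 + g$z^2, d)
  gtv <- rad2 <= 1
  # recurrence: ellipsoid cap holding rec_fraction of the unit-ball volume;
  # in normalized coordinates the cut plane u.x >= t with cap fraction
  # (2 - 3t + t^3)/4
  u <- spec$rec_direction / sqrt(sum(spec$rec_direction^2))
  t_cut <- stats::uniroot(function(t) (2 - 3 * t + t^3) / 4 -
                            spec$rec_fraction,
                          interval = c(-1, 1), tol = 1e-10)$root
  proj <- array(g$x * u[1] + g$y * u[2] + g$z * u[3], d)
  rec <- gtv & proj >= t_cut
  bg <- spec$background_mean +
    spec$background_sd * correlated_field(d, sp, 3)
  ctrl <- spec$gtv_mean + spec$control_sd *
    correlated_field(d, sp, spec$control_corr)
  vol <- bg
  vol[gtv] <- ctrl[gtv]
  if (spec$effect_size > 1) {
    # additive heterogeneity excess: SD ratio rec/control = effect_size
    excess <- spec$control_sd * sqrt(spec$effect_size^2 - 1) *
      correlated_field(d, sp, spec$rec_corr)
    vol[rec] <- vol[rec] + excess[rec]
  }
  list(vol = image_volume(vol, sp), gtv = roi_mask(gtv, sp),
       rec = roi_mask(rec, sp))
}

#' Specification of a synthetic patient cohort
#'
#' Defaults follow the emulated clinical cohort structure: 28
#' training and 12 validation patients, with the recurrent fraction of the
#' GTV sampled log-uniformly over 2%-71% (giving a mean near 20%).
#'
#' @param n_train,n_val cohort sizes (defaults 28 and 12).
#' @param semiaxis_range GTV semi-axis sampling range in mm (default 10-28,
#'   spanning the order-of-magnitude spread of primary tumor volumes seen
#'   clinically; the wide spread makes recurrent and control region sizes
#'   overlap across the cohort, so region size itself is not a label
#'   surrogate).
#' @param rec_fraction_range recurrence fraction range (default 0.02-0.71,
#'   sampled log-uniformly).
#' @param effect_size recurrent/control noise-SD ratio (default 2).
#' @param shape,spacing per-patient grid (as in [phantom_spec()]).
#' @param seed master seed; per-patient seeds are derived from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_train = 28, n_val = 12,
                        semiaxis_range = c(10, 28),
                        rec_fraction_range = c(0.02, 0.71),
                        effect_size = 2, shape = c(64, 64, 28),
                        spacing = c(1, 1, 3), seed = 1) {
  structure(list(n_train = n_train, n_val = n_val,
                 semiaxis_range = semiaxis_range,
                 rec_fraction_range = rec_fraction_range,
                 effect_size = effect_size, shape = shape,
                 spacing = spacing, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws per-patient phantom parameters from the cohort spec and generates
#' each phantom with a seed derived from the master seed, so the cohort is
#' reproducible across machines.
#'
#' @param spec a [cohort_spec()].
#' @return A `cohort`: list with `patients` (each with `id`, `split`,
#'   `spec`, `vol`, `gtv`, `rec`) and `manifest` (data.frame of per-patient
#'   ground truth: split, semi-axes, recurrence fraction, seed).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_train + spec$n_val
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)
  seeds <- sample.int(2^30, n)
  semi <- matrix(stats::runif(3 * n, spec$semiaxis_range[1],
                              spec$semiaxis_range[2]), n, 3)
  lf <- log(spec$rec_fraction_range)
  fracs <- exp(stats::runif(n, lf[1], lf[2]))
  dirs <- matrix(stats::rnorm(3 * n), n, 3)
  splits <- rep(c("train", "validation"), c(spec$n_train, spec$n_val))
  patients <- lapply(seq_len(n), function(i) {
    ps <- phantom_spec(shape = spec$shape, spacing = spec$spacing,
                       gtv_semiaxes = semi[i, ], rec_fraction = fracs[i],
                       rec_direction = dirs[i, ],
                       effect_size = spec$effect_size, seed = seeds[i])
    ph <- generate_phantom(ps)
    c(list(id = sprintf("pt%02d", i), split = splits[i], spec = ps), ph)
  })
  manifest <- data.frame(
    patient_id = vapply(patients, `[[`, character(1), "id"),
    split = splits,
    semiaxis_x = semi[, 1], semiaxis_y = semi[, 2], semiaxis_z = semi[, 3],
    rec_fraction = fracs, effect_size = spec$effect_size, seed = seeds)
  structure(list(patients = patients, manifest = manifest,
                 spec = spec), class = "cohort")
}

#' Write a cohort to disk as NIfTI triplets plus a manifest
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Files are `<id>_ct.nii.gz`, `<id>_gtv.nii.gz`,
#'   `<id>_rec.nii.gz` and `manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort$patients) {
    write_volume(p$vol, file.path(dir, paste0(p$id, "_ct.nii.gz")))
    write_volume(p$gtv, file.path(dir, paste0(p$id, "_gtv.nii.gz")))
    write_volume(p$rec, file.path(dir, paste0(p$id, "_rec.nii.gz")))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and NIfTI triplets.
#' @return A `cohort` (without per-patient specs).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  patients <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$patient_id[i]
    vol <- read_volume(file.path(dir, paste0(id, "_ct.nii.gz")))
    list(id = id, split = manifest$split[i], spec = NULL, vol = vol,
         gtv = read_mask(file.path(dir, paste0(id, "_gtv.nii.gz")), vol),
         rec = read_mask(file.path(dir, paste0(id, "_rec.nii.gz")), vol))
  })
  structure(list(patients = patients, manifest = manifest, spec = NULL),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d patients (%d train / %d validation)\n",
              nrow(x$manifest), sum(x$manifest$split == "train"),
              sum(x$manifest$split == "validation")))
  invisible(x)
}
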