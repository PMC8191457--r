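# End-to-end study pipelines: bi-regional differentiation, local
# fixed-count detection, and local fixed-size LOOCV.

#' Analysis configuration
#'
#' Bundles every constant of the analysis; unknown keys are rejected so a
#' typo cannot silently fall back to a default. The resolved configuration
#' is echoed into every pipeline report.
#'
#' @param ... overrides of the defaults: `target_spacing` (3.3 mm),
#'   `window_low`/`window_high` (-20/180 HU), `min_voxels` (27),
#'   `bin_width` (5 HU), `pet_fraction` (0.4), `partition_k` (8),
#'   `grid_size`/`grid_shift`/`grid_min_voxels` (5/5/25),
#'   `label_threshold` (0.5, strict), `r_max` (0.5), `alpha` (0.05),
#'   `n_perm` (1000), `bootstrap_B` (2000), `cutoff_percentile` (0.75),
#'   `seed` (1).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    target_spacing = 3.3, window_low = -20, window_high = 180,
    min_voxels = 27, bin_width = 5, pet_fraction = 0.4,
    partition_k = 8, grid_size = 5, grid_shift = 5, grid_min_voxels = 25,
    label_threshold = 0.5, r_max = 0.5, alpha = 0.05, n_perm = 1000,
    bootstrap_B = 2000, cutoff_percentile = 0.75, seed = 1)
  overrides <- list(...)
  if (length(overrides) == 1 && is.list(overrides[[1]]) &&
      is.null(names(overrides)))
    overrides <- overrides[[1]]
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "run_config")
}

#' Load a configuration from a YAML file
#'
#' @param path YAML file whose keys are [run_config()] keys.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' Bring one patient to the analysis grid
#'
#' Resamples the image (trilinear) and the masks (nearest-neighbor) to the
#' isotropic analysis grid, derives the recurrent/control region pair, and
#' applies the HU window over the GTV.
#'
#' @param vol CT [image_volume()].
#' @param gtv,rec GTV and recurrence [roi_mask()] objects on `vol`'s grid.
#' @param config a [run_config()].
#' @param artifact_slices optional z slices (on the resampled grid) cleared
#'   from the GTV before analysis.
#' @return List with `mv` (windowed `masked_volume` over the GTV), `gtv`,
#'   `gtv_rec`, `gtv_control` (resampled masks).
#' @export
prepare_patient <- function(vol, gtv, rec, config = run_config(),
                            artifact_slices = integer(0)) {
  rvol <- resample_isotropic(vol, config$target_spacing)
  rgtv <- resample_mask(gtv, config$target_spacing)
  rrec <- resample_mask(rec, config$target_spacing)
  if (length(artifact_slices))
    rgtv <- remove_artifact_slices(rgtv, artifact_slices)
  pair <- derive_region_pair(rgtv, rrec)
  mv <- apply_hu_window(rvol, rgtv, config$window_low, config$window_high)
  list(mv = mv, gtv = rgtv, gtv_rec = pair$rec, gtv_control = pair$control)
}

# Feature rows for the two bi-regional regions of one patient, or NULL with
# a reason when a region fails the minimum-volume rule.
biregional_rows <- function(prep, vol, config, id, split) {
  rows <- list()
  for (lab in c("recurrent", "control")) {
    region <- if (lab == "recurrent") prep$gtv_rec else prep$gtv_control
    mv <- prep$mv
    mv$data[!region$data] <- NA_real_
    mv$roi_voxel_count <- sum(!is.na(mv$data))
    if (mv$roi_voxel_count < config$min_voxels)
      return(list(rows = NULL,
                  reason = sprintf("%s region of %s has %d voxels < %d",
                                   lab, id, mv$roi_voxel_count,
                                   config$min_voxels)))
    fv <- extract_feature_vector(mv, config$bin_width, config$min_voxels)
    rows[[lab]] <- data.frame(patient_id = id, split = split,
                              region_id = lab, label = lab,
                              roi_voxel_count = mv$roi_voxel_count,
                              as.list(fv), check.names = FALSE)
  }
  list(rows = do.call(rbind, rows), reason = NULL)
}

evaluate_split <- function(model, table, config, seed_offset = 0) {
  pred <- apply_model(model, table)
  if (length(unique(table$label)) < 2)
    return(list(auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                B = config$bootstrap_B, sensitivity = NA_real_,
                specificity = NA_real_, note = "single-class split"))
  bootstrap_auc_ci(table$label, pred, B = config$bootstrap_B,
                   seed = config$seed + seed_offset, cutoff = model$cutoff)
}

#' Bi-regional radiomics pipeline
#'
#' Extracts one feature vector per region (recurrent `GTVrec` and control
#' `GTVcontrol`) and patient, trains the selection cascade on the training
#' split, and evaluates on the validation split: a differentiation task
#' between recurrent and controlled sub-volumes.
#'
#' @param cohort a `cohort` (see [generate_cohort()] / [read_cohort()]).
#' @param config a [run_config()].
#' @return List with `model`, `selection`, `table`, `train` and
#'   `validation` evaluation (AUC, bootstrap CI, sensitivity/specificity at
#'   the cut-off), `log` (exclusions), and the resolved `config`.
#' @export
run_biregional <- function(cohort, config = run_config()) {
  log <- character(0)
  rows <- list()
  for (p in cohort$patients) {
    prep <- prepare_patient(p$vol, p$gtv, p$rec, config)
    br <- biregional_rows(prep, p$vol, config, p$id, p$split)
    if (is.null(br$rows)) {
      log <- c(log, sprintf("dropped patient %s: %s", p$id, br$reason))
      next
    }
    rows[[p$id]] <- br$rows
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  train <- table[table$split == "train", , drop = FALSE]
  val <- table[table$split == "validation", , drop = FALSE]
  res <- run_selection_cascade(train, r_max = config$r_max,
                               alpha = config$alpha, n_perm = config$n_perm,
                               cutoff_percentile = config$cutoff_percentile,
                               seed = config$seed)
  out <- list(model = res$model, selection = res$selection, table = table,
              train = evaluate_split(res$model, train, config, 0),
              validation = if (nrow(val))
                evaluate_split(res$model, val, config, 1) else NULL,
              log = log, config = config)
  class(out) <- "radiomics_report"
  out
}

# Shared worker for partition-based pipelines: per-patient labeled feature
# table plus partition bookkeeping.
partition_tables <- function(cohort, config, scheme) {
  out <- list()
  log <- character(0)
  for (p in cohort$patients) {
    prep <- prepare_patient(p$vol, p$gtv, p$rec, config)
    part <- tryCatch(
      if (scheme == "fixed_count")
        partition_fixed_count(prep$gtv, config$partition_k)
      else
        partition_fixed_size(prep$gtv, config$grid_size, config$grid_shift,
                             config$grid_min_voxels),
      error = function(e) e)
    if (inherits(part, "error")) {
      log <- c(log, sprintf("dropped patient %s: %s", p$id,
                            conditionMessage(part)))
      next
    }
    part <- label_subregions(part, prep$gtv_rec, config$label_threshold)
    min_vox <- if (scheme == "fixed_count") config$min_voxels
               else config$grid_min_voxels
    tab <- build_feature_table(prep$mv, part, patient_id = p$id,
                               bin_width = config$bin_width,
                               min_voxels = min_vox)
    for (dr in attr(tab, "dropped"))
      log <- c(log, sprintf("patient %s sub-region %s dropped: %s",
                            p$id, dr$region_id, dr$reason))
    if (nrow(tab) == 0) next
    tab$split <- p$split
    out[[p$id]] <- list(table = tab, partition = part, prep = prep)
  }
  list(per_patient = out, log = log)
}

#' Local radiomics with a fixed number of sub-regions (detection task)
#'
#' Partitions each GTV into 8 octants, labels each sub-region recurrent
#' when it overlaps the recurrence by more than the labeling threshold,
#' trains the cascade on the training split, and evaluates detection on the
#' validation split — including, per validation patient with at least one
#' true recurrent sub-region, whether at least one was correctly classified
#' and what fraction of the recurrence volume the detected sub-regions
#' cover.
#'
#' @param cohort a `cohort`.
#' @param config a [run_config()].
#' @return List as in [run_biregional()], plus `detection` (per-patient
#'   data.frame).
#' @export
run_local_fixed_count <- function(cohort, config = run_config()) {
  pt <- partition_tables(cohort, config, "fixed_count")
  table <- do.call(rbind, c(lapply(pt$per_patient, `[[`, "table"),
                            list(make.row.names = FALSE)))
  train <- table[table$split == "train", , drop = FALSE]
  val <- table[table$split == "validation", , drop = FALSE]
  res <- run_selection_cascade(train, r_max = config$r_max,
                               alpha = config$alpha, n_perm = config$n_perm,
                               cutoff_percentile = config$cutoff_percentile,
                               seed = config$seed)
  detection <- list()
  for (id in names(pt$per_patient)) {
    pp <- pt$per_patient[[id]]
    if (pp$table$split[1] != "validation") next
    truly_rec <- pp$table$label == "recurrent"
    if (!any(truly_rec)) next
    pred <- apply_model(res$model, pp$table)
    called <- pred >= res$model$cutoff
    rec_total <- sum(pp$prep$gtv_rec$data)
    detected_vox <- 0
    for (i in which(called)) {
      s <- pp$partition$subregions[[pp$table$region_id[i]]]
      detected_vox <- detected_vox + sum(pp$prep$gtv_rec$data[s$voxels])
    }
    detection[[id]] <- data.frame(
      patient_id = id, n_recurrent_subregions = sum(truly_rec),
      any_detected = any(called & truly_rec),
      detected_recurrence_fraction =
        if (rec_total > 0) detected_vox / rec_total else NA_real_)
  }
  out <- list(model = res$model, selection = res$selection, table = table,
              train = evaluate_split(res$model, train, config, 0),
              validation = if (nrow(val))
                evaluate_split(res$model, val, config, 1) else NULL,
              detection = if (length(detection))
                do.call(rbind, c(detection, list(make.row.names = FALSE)))
                else NULL,
              log = pt$log, config = config)
  class(out) <- "radiomics_report"
  out
}

#' Local radiomics with fixed-size sub-regions, patient-level LOOCV
#'
#' Partitions each GTV by the optimized fixed-size grid, labels the cells,
#' and runs the whole cascade in leave-one-patient-out cross-validation
#' over the patients that contribute both sub-region classes. Folds with
#' fewer than 3 held-out sub-volumes or with recurrence involvement above
#' 25% in most sub-volumes are flagged as diagnostic context for AUCs below
#' 0.5.
#'
#' @param cohort a `cohort`.
#' @param config a [run_config()].
#' @return List with `loocv` (per-fold AUCs and mean), `folds` (per-fold
#'   context data.frame), `table`, `log`, `config`.
#' @export
run_local_fixed_size_loocv <- function(cohort, config = run_config()) {
  pt <- partition_tables(cohort, config, "fixed_size")
  table <- do.call(rbind, c(lapply(pt$per_patient, `[[`, "table"),
                            list(make.row.names = FALSE)))
  cv <- loocv_patient(table, r_max = config$r_max, alpha = config$alpha,
                      n_perm = config$n_perm,
                      cutoff_percentile = config$cutoff_percentile,
                      seed = config$seed)
  folds <- do.call(rbind, lapply(cv$fold_details, function(f) {
    frac_involved <- mean(
      table$overlap_fraction[table$patient_id == f$patient] > 0.25)
    data.frame(patient_id = f$patient, auc = f$auc, n_subvolumes = f$n_test,
               n_recurrent = f$n_test_recurrent,
               small_fold = f$n_test < 3,
               high_involvement = frac_involved > 0.5)
  }))
  log <- c(pt$log,
           sprintf("excluded from LOOCV (single-class sub-volumes): %s",
                   paste(cv$excluded_patients, collapse = ", ")))
  out <- list(loocv = cv, folds = folds, table = table, log = log,
              config = config)
  class(out) <- "radiomics_report"
  out
}

#' @export
print.radiomics_report <- function(x, ...) {
  if (!is.null(x$loocv)) {
    cat(sprintf("LOOCV over %d folds: mean AUC %.3f (%d folds < 0.5)\n",
                x$loocv$n_folds, x$loocv$mean_auc,
                sum(x$loocv$fold_aucs < 0.5, na.rm = TRUE)))
  } else {
    cat(sprintf("model: %s\n",
                if (length(x$model$features))
                  paste(x$model$features, collapse = ", ")
                else "(intercept only)"))
    cat(sprintf("train AUC %.3f (95%% CI %.3f-%.3f)\n", x$train$auc,
                x$train$ci_low, x$train$ci_high))
    if (!is.null(x$validation))
      cat(sprintf("validation AUC %.3f (95%% CI %.3f-%.3f), sens %.2f, spec %.2f\n",
                  x$validation$auc, x$validation$ci_low,
                  x$validation$ci_high, x$validation$sensitivity,
                  x$validation$specificity))
  }
  if (length(x$log)) cat(sprintf("%d logged exclusions\n", length(x$log)))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' @param model a `logistic_model`.
#' @param path output path.
#' @param config optional [run_config()] echoed into the file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, config = NULL) {
  obj <- list(features = model$features,
              coefficients = as.list(model$coefficients),
              intercept = model$intercept, cutoff = model$cutoff,
              aic = model$fit$aic)
  if (!is.null(config)) obj$config <- unclass(config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
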