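# Logistic modeling: ridge-stabilized fits, backward-AIC elimination,
# thresholding, stratified bootstrap CIs, and patient-level LOOCV.

# Logistic regression by IRLS with a tiny L2 penalty (default 1e-6, not
# applied to the intercept). The penalty only matters under (near) perfect
# separation, where the unpenalized MLE diverges; reported log-likelihood
# and AIC are the unpenalized quantities at the returned coefficients.
stable_logistic <- function(x, y, penalty = 1e-6, maxit = 100,
                            tol = 1e-10) {
  x <- as.matrix(x)
  n <- nrow(x)
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  pen <- c(0, rep(penalty, p - 1))
  beta <- rep(0, p)
  yn <- as.numeric(y)
  separated <- FALSE
  pll <- function(b) {
    mu <- stats::plogis(drop(X %*% b))
    sum(yn * log(pmax(mu, 1e-300)) + (1 - yn) * log(pmax(1 - mu, 1e-300))) -
      sum(pen * b^2) / 2
  }
  obj <- pll(beta)
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X, yn - mu)) - pen * beta
    H <- crossprod(X, X * w) + diag(pen, p)
    step <- tryCatch(solve(H, grad), error = function(e) rep(0, p))
    # damped Newton: halve the step until the penalized likelihood improves
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      obj_new <- pll(beta_new)
      if (obj_new >= obj - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new
    obj <- obj_new
    if (max(abs(beta)) > 50) separated <- TRUE
    if (moved < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  ll <- sum(yn * log(pmax(mu, 1e-300)) +
              (1 - yn) * log(pmax(1 - mu, 1e-300)))
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- crossprod(X, X * w) + diag(pen, p)
  se <- sqrt(diag(tryCatch(solve(H), error = function(e)
    diag(Inf, p))))
  zval <- beta / se
  pvals <- 2 * stats::pnorm(-abs(zval))
  list(coefficients = stats::setNames(beta, colnames(X)),
       fitted = mu, loglik = ll, aic = 2 * p - 2 * ll,
       se = se, p_values = stats::setNames(pvals, colnames(X)),
       separated = separated, n = n)
}

#' Backward-AIC multivariable logistic regression
#'
#' Starts from the model containing all candidate features and iteratively
#' removes the feature whose removal most decreases the AIC
#' (\eqn{2k - 2\log L}), stopping when no removal decreases it. Fits are
#' ridge-stabilized (penalty 1e-6) so that perfect separation does not
#' derail the elimination; a warning is recorded when stabilization was
#' active. The intercept-only model is a legal outcome.
#'
#' @param x feature matrix/data.frame of candidate features.
#' @param labels binary labels (`TRUE`/`"recurrent"` = positive).
#' @return A `logistic_model`: list with `features`, `coefficients` (named,
#'   without intercept), `intercept`, `aic_path` (data.frame of steps),
#'   `fit` (final `stable_logistic` output), `cutoff` (NA until set).
#' @export
fit_backward_aic <- function(x, labels) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  x <- as.matrix(x)
  feats <- colnames(x)
  if (length(feats) < 1) stop("need at least 1 candidate feature")
  current <- feats
  fit <- stable_logistic(x[, current, drop = FALSE], y)
  path <- data.frame(step = 0L, removed = NA_character_, aic = fit$aic,
                     n_features = length(current))
  step_i <- 0L
  repeat {
    if (length(current) == 0) break
    cand <- lapply(seq_along(current), function(i) {
      rest <- current[-i]
      f <- if (length(rest)) stable_logistic(x[, rest, drop = FALSE], y)
      else stable_logistic(matrix(numeric(0), nrow(x), 0), y)
      list(drop = current[i], fit = f)
    })
    aics <- vapply(cand, function(cc) cc$fit$aic, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= fit$aic - 1e-12) break
    step_i <- step_i + 1L
    current <- setdiff(current, cand[[best]]$drop)
    fit <- cand[[best]]$fit
    path <- rbind(path, data.frame(step = step_i,
                                   removed = cand[[best]]$drop,
                                   aic = fit$aic,
                                   n_features = length(current)))
  }
  cf <- fit$coefficients
  structure(list(features = current,
                 coefficients = cf[setdiff(names(cf), "(Intercept)")],
                 intercept = unname(cf["(Intercept)"]),
                 aic_path = path, fit = fit, cutoff = NA_real_),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("logistic_model: %d features, AIC %.2f, cutoff %s\n",
              length(x$features), x$fit$aic,
              if (is.na(x$cutoff)) "unset" else sprintf("%.3f", x$cutoff)))
  if (length(x$features)) {
    for (f in x$features)
      cat(sprintf("  %s: %+.4g\n", f, x$coefficients[f]))
  }
  cat(sprintf("  (Intercept): %+.4g\n", x$intercept))
  invisible(x)
}

#' Predicted recurrence probability
#'
#' Evaluates \eqn{p = 1/(1 + \exp(-(\beta_0 + \sum_i \beta_i x_i)))} on new
#' rows.
#'
#' @param model a `logistic_model`.
#' @param newdata data.frame/matrix containing the model's feature columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
apply_model <- function(model, newdata) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(model$features, colnames(newdata))
  if (length(missing))
    stop(sprintf("missing model features: %s", paste(missing, collapse = ", ")))
  eta <- rep(model$intercept, nrow(newdata))
  if (length(model$features))
    eta <- eta + drop(as.matrix(newdata[, model$features, drop = FALSE]) %*%
                        model$coefficients[model$features])
  stats::plogis(eta)
}

#' Classification cut-off from training predictions
#'
#' The 75th percentile of training-cohort predictions (linear-interpolation
#' percentile rule); a region is classified recurrent when its predicted
#' probability is at or above the cut-off, so about the top quarter of
#' training regions is called recurrent.
#'
#' @param train_predictions numeric vector of predicted probabilities.
#' @param probs percentile (default 0.75).
#' @return The cut-off probability.
#' @export
classification_cutoff <- function(train_predictions, probs = 0.75) {
  if (length(train_predictions) == 0) stop("no predictions")
  pctl(train_predictions, probs)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples positives and negatives separately (preserving the class
#' counts of every replicate), computes the rank-based AUC per replicate,
#' and reports the percentile interval.
#'
#' @param labels binary labels.
#' @param predictions numeric scores.
#' @param B number of replicates (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @param cutoff optional classification cut-off; when given, sensitivity
#'   and specificity at the cut-off (ties classified positive) are included.
#' @param keep_replicates return the per-replicate AUCs as
#'   `replicate_aucs`.
#' @return List with `auc`, `ci_low`, `ci_high`, `B`, `stratified_ok`
#'   (every replicate preserved the class counts), and optionally
#'   `sensitivity`/`specificity` and `replicate_aucs`.
#' @export
bootstrap_auc_ci <- function(labels, predictions, B = 2000, level = 0.95,
                             seed = 1, cutoff = NULL,
                             keep_replicates = FALSE) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) stop("need both classes")
  ipos <- which(y); ineg <- which(!y)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  counts_ok <- TRUE
  reps <- vapply(seq_len(B), function(b) {
    sp <- ipos[sample.int(length(ipos), length(ipos), replace = TRUE)]
    sn <- ineg[sample.int(length(ineg), length(ineg), replace = TRUE)]
    idx <- c(sp, sn)
    if (sum(y[idx]) != length(ipos) || sum(!y[idx]) != length(ineg))
      counts_ok <<- FALSE
    auc_rank(y[idx], predictions[idx])
  }, numeric(1))
  a <- (1 - level) / 2
  out <- list(auc = auc_rank(y, predictions),
              ci_low = pctl(reps, a), ci_high = pctl(reps, 1 - a), B = B,
              stratified_ok = counts_ok)
  if (keep_replicates) out$replicate_aucs <- reps
  if (!is.null(cutoff)) {
    called <- predictions >= cutoff
    out$sensitivity <- sum(called & y) / sum(y)
    out$specificity <- sum(!called & !y) / sum(!y)
  }
  out
}

#' Run the full selection and modeling cascade on a feature table
#'
#' Voxel-count correlation filter, parallel-analysis component retention,
#' Spearman grouping, per-group univariate-AUC representatives, and
#' backward-AIC multivariable logistic regression; finally the 75th
#' percentile classification cut-off on the training predictions. When
#' parallel analysis retains no component, the first component is used as a
#' single group (the grouping step needs at least one).
#'
#' @param table feature table (rows = regions) with `label` and
#'   `roi_voxel_count`.
#' @param r_max voxel-correlation exclusion threshold (default 0.5).
#' @param alpha representative p-value threshold (default 0.05).
#' @param n_perm parallel-analysis permutations (default 1000).
#' @param cutoff_percentile classification percentile (default 0.75).
#' @param seed integer seed.
#' @return List with `model` (a `logistic_model` with cut-off set),
#'   `selection` (filter + grouping + representative details), and
#'   `train_predictions`.
#' @export
run_selection_cascade <- function(table, r_max = 0.5, alpha = 0.05,
                                  n_perm = 1000, cutoff_percentile = 0.75,
                                  seed = 1) {
  filt <- filter_voxel_correlation(table, r_max = r_max)
  if (length(filt$retained) < 2)
    stop("fewer than 2 features survive the voxel-correlation filter")
  x <- as.matrix(table[, filt$retained, drop = FALSE])
  horn <- horn_retained_components(x, n_perm = n_perm, seed = seed)
  k <- max(horn$n_retained, 1L)
  groups <- group_by_component(x[, horn$feature_names, drop = FALSE],
                               horn$scores[, seq_len(k), drop = FALSE])
  reps <- select_representatives(x[, horn$feature_names, drop = FALSE],
                                 groups, table$label, alpha = alpha)
  if (nrow(reps) == 0) {
    fit0 <- stable_logistic(matrix(numeric(0), nrow(table), 0),
                            as_binary_label(table$label))
    model <- structure(list(features = character(0),
                            coefficients = numeric(0),
                            intercept = unname(fit0$coefficients[1]),
                            aic_path = data.frame(step = 0L,
                                                  removed = NA_character_,
                                                  aic = fit0$aic,
                                                  n_features = 0L),
                            fit = fit0, cutoff = NA_real_),
                       class = "logistic_model")
  } else {
    model <- fit_backward_aic(x[, reps$feature, drop = FALSE], table$label)
  }
  preds <- apply_model(model, table)
  model$cutoff <- classification_cutoff(preds, cutoff_percentile)
  list(model = model,
       selection = list(filter = filt, n_components = horn$n_retained,
                        groups = groups, representatives = reps),
       train_predictions = preds)
}

#' Patient-level leave-one-out cross-validation
#'
#' For each patient, the entire cascade ([run_selection_cascade()]) is rerun
#' on the remaining patients' sub-regions and the held-out patient's
#' sub-regions are predicted; the fold AUC is the rank-based AUC of those
#' predictions. Only patients contributing both classes enter (others are
#' listed in `excluded_patients`, mirroring the eligibility requirement of
#' patient-level LOOCV); folds whose held-out rows are single-class report
#' `NA` AUC rather than being dropped.
#'
#' @param table feature table with `patient_id` and `label`.
#' @param ... passed to [run_selection_cascade()].
#' @return List with `fold_aucs` (named per patient), `mean_auc` (over
#'   defined folds), `n_folds`, `excluded_patients`, `fold_details`.
#' @export
loocv_patient <- function(table, ...) {
  split_tab <- split(seq_len(nrow(table)), table$patient_id)
  both <- vapply(split_tab, function(i)
    length(unique(table$label[i])) == 2, logical(1))
  eligible <- names(split_tab)[both]
  if (length(eligible) < 3)
    stop("need >= 3 patients with both sub-region classes")
  tab <- table[table$patient_id %in% eligible, , drop = FALSE]
  folds <- lapply(eligible, function(pid) {
    test <- tab[tab$patient_id == pid, , drop = FALSE]
    train <- tab[tab$patient_id != pid, , drop = FALSE]
    res <- run_selection_cascade(train, ...)
    pred <- apply_model(res$model, test)
    list(patient = pid,
         auc = auc_rank(as_binary_label(test$label), pred),
         n_test = nrow(test),
         n_test_recurrent = sum(as_binary_label(test$label)),
         features = res$model$features)
  })
  aucs <- stats::setNames(vapply(folds, function(f) f$auc, numeric(1)),
                          eligible)
  list(fold_aucs = aucs, mean_auc = mean(aucs, na.rm = TRUE),
       n_folds = length(folds),
       excluded_patients = names(split_tab)[!both],
       fold_details = folds)
}
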