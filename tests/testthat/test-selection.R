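test_that("voxel-count filter removes size-linked and constant features", {
  tab <- toy_feature_table(n = 60, seed = 2)
  tab$stat_mean <- tab$roi_voxel_count            # r = 1
  tab$stat_variance <- -tab$roi_voxel_count       # r = -1 (absolute value)
  tab$stat_median <- 5                            # constant
  out <- filter_voxel_correlation(tab)
  expect_false("stat_mean" %in% out$retained)
  expect_false("stat_variance" %in% out$retained)
  expect_false("stat_median" %in% out$retained)
  expect_error(filter_voxel_correlation(tab[1:2, ]), "3 rows")
})

test_that("features independent of voxel count are retained", {
  set.seed(3)
  n <- 500
  tab <- data.frame(roi_voxel_count = round(runif(n, 30, 300)),
                    stat_mean = rnorm(n), check.names = FALSE)
  out <- filter_voxel_correlation(tab)
  expect_true("stat_mean" %in% out$retained)
  expect_lt(abs(out$r["stat_mean"]), 0.2)
})

test_that("parallel analysis retains the number of true factors", {
  set.seed(10)
  n <- 200
  # one dominant latent factor driving 8 of 10 features
  f1 <- rnorm(n)
  x1 <- cbind(sapply(1:8, function(i) 0.9 * f1 + sqrt(1 - 0.81) * rnorm(n)),
              matrix(rnorm(n * 2), n, 2))
  h1 <- horn_retained_components(x1, n_perm = 200, seed = 4)
  expect_equal(h1$n_retained, 1)
  # two orthogonal strong factors
  f2 <- rnorm(n)
  x2 <- cbind(sapply(1:5, function(i) 0.9 * f1 + 0.44 * rnorm(n)),
              sapply(1:5, function(i) 0.9 * f2 + 0.44 * rnorm(n)))
  h2 <- horn_retained_components(x2, n_perm = 200, seed = 4)
  expect_equal(h2$n_retained, 2)
  # independent noise: at most 1 component in most seeds
  retained <- vapply(1:10, function(s) {
    horn_retained_components(matrix(rnorm(200 * 10), 200, 10),
                             n_perm = 100, seed = s)$n_retained
  }, integer(1))
  expect_gte(mean(retained <= 1), 0.9)
  expect_error(horn_retained_components(matrix(1, 10, 3)), "degenerate")
})

test_that("features group to the component they track, Spearman-invariantly", {
  set.seed(12)
  n <- 100
  scores <- matrix(rnorm(2 * n), n, 2)
  x <- cbind(a = scores[, 1],                  # equals PC1 scores
             b = exp(scores[, 2]),             # monotone transform of PC2
             c = rnorm(n))                     # uncorrelated, still assigned
  g <- group_by_component(x, scores)
  expect_equal(unname(g[c("a", "b")]), c(1L, 2L))
  expect_true(g["c"] %in% c(1L, 2L))
})

test_that("representatives maximize AUC under the p < 0.05 gate", {
  set.seed(13)
  n <- 200
  y <- rep(c("control", "recurrent"), each = n / 2)
  strong <- ifelse(y == "recurrent", 2, 0) + rnorm(n, sd = 0.8)
  weak <- ifelse(y == "recurrent", 0.6, 0) + rnorm(n)
  flat <- rep(3.14, n) + rnorm(n, sd = 1e-8)  # near-constant, uninformative
  x <- cbind(stat_mean = weak, stat_variance = strong, stat_median = flat)
  groups <- stats::setNames(c(1L, 1L, 2L), colnames(x))
  reps <- select_representatives(x, groups, y)
  expect_equal(reps$feature[reps$group == 1], "stat_variance")
  expect_true(all(reps$p_value < 0.05))
  expect_false("stat_median" %in% reps$feature)
  # perfect separation: AUC 1 and still selected (ridge-stabilized fit)
  sep <- ifelse(y == "recurrent", 5, -5)
  reps2 <- select_representatives(cbind(stat_mean = sep),
                                  stats::setNames(1L, "stat_mean"), y)
  expect_equal(reps2$auc, 1)
  expect_error(select_representatives(x, groups, rep("control", n)),
               "both classes")
})

test_that("backward AIC eliminates noise and keeps signal", {
  keep_signal <- 0
  for (s in 1:25) {
    set.seed(s)
    n <- 300
    y <- rbinom(n, 1, 0.5)
    signal <- ifelse(y == 1, 1, 0) * 2 + rnorm(n)
    noise <- rnorm(n)
    m <- fit_backward_aic(cbind(sig = signal, noi = noise), y == 1)
    if (identical(m$features, "sig")) keep_signal <- keep_signal + 1
    expect_true(all(diff(m$aic_path$aic) < 0))  # AIC strictly decreasing along path
  }
  # AIC retains a pure-noise variable with chi-square(1) > 2 probability
  # (~0.16), so perfect elimination is not expected
  expect_gte(keep_signal / 25, 0.8)
  # all-noise candidates may legally collapse to intercept-only
  set.seed(99)
  y <- rbinom(200, 1, 0.5)
  m0 <- fit_backward_aic(matrix(rnorm(600), 200, 3,
                                dimnames = list(NULL, c("a", "b", "c"))),
                         y == 1)
  expect_true(length(m0$features) <= 3)
})

test_that("ridge-stabilized fit agrees with glm away from separation", {
  set.seed(14)
  n <- 150
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
  y <- rbinom(n, 1, plogis(0.5 + x[, 1] - 0.7 * x[, 2]))
  ours <- localradiomics:::stable_logistic(x, y)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(ours$coefficients), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(ours$aic, AIC(ref), tolerance = 1e-6)
})

test_that("model predictions follow the logistic form", {
  m <- structure(list(
    features = c("glrlm_averaged_gray_level_nonuniformity",
                 "glcm_merged_sum_entropy"),
    coefficients = c(glrlm_averaged_gray_level_nonuniformity = 141.43,
                     glcm_merged_sum_entropy = 4.56),
    intercept = -32.64, cutoff = NA_real_), class = "logistic_model")
  nd <- data.frame(glrlm_averaged_gray_level_nonuniformity = 0.2,
                   glcm_merged_sum_entropy = 1.0, check.names = FALSE)
  expect_equal(apply_model(m, nd), plogis(-32.64 + 141.43 * 0.2 + 4.56),
               tolerance = 1e-12)
  # linear predictor 0 -> probability one half
  m0 <- structure(list(features = character(0), coefficients = numeric(0),
                       intercept = 0, cutoff = NA_real_),
                  class = "logistic_model")
  expect_equal(apply_model(m0, nd), 0.5)
  # monotone in a positive-coefficient feature
  nd2 <- nd; nd2[[1]] <- nd[[1]] + 0.01
  expect_gt(apply_model(m, nd2), apply_model(m, nd))
  expect_error(apply_model(m, nd[, -1, drop = FALSE]), "missing")
})

test_that("classification cut-off is the 75th percentile of train predictions", {
  expect_equal(classification_cutoff(c(0.1, 0.2, 0.3, 0.4)),
               unname(quantile(c(0.1, 0.2, 0.3, 0.4), 0.75, type = 7)))
  expect_equal(classification_cutoff(rep(0.42, 10)), 0.42)
  set.seed(15)
  p <- runif(400)  # no ties: about a quarter at or above the cut-off
  expect_equal(mean(p >= classification_cutoff(p)), 0.25, tolerance = 0.01)
})

test_that("stratified bootstrap preserves class counts and matches pROC", {
  set.seed(16)
  y <- rep(c(TRUE, FALSE), times = c(30, 70))
  pr <- ifelse(y, rnorm(100, 1), rnorm(100))
  expect_equal(localradiomics:::auc_rank(y, pr),
               as.numeric(suppressMessages(pROC::auc(y, pr))),
               tolerance = 1e-12)
  # stratification contract: every replicate has the original class counts
  ipos <- which(y); ineg <- which(!y)
  set.seed(1)
  for (b in 1:50) {
    idx <- c(sample(ipos, length(ipos), TRUE), sample(ineg, length(ineg), TRUE))
    expect_equal(sum(y[idx]), 30)
  }
  ci <- bootstrap_auc_ci(y, pr, B = 500, seed = 3)
  expect_lte(ci$ci_low, ci$auc)
  expect_gte(ci$ci_high, ci$auc)
  # perfect separation: degenerate interval at 1
  ysep <- rep(c(TRUE, FALSE), each = 20)
  psep <- ifelse(ysep, 1, 0)
  cis <- bootstrap_auc_ci(ysep, psep, B = 200, seed = 4)
  expect_equal(c(cis$auc, cis$ci_low, cis$ci_high), c(1, 1, 1))
  # reproducible under a seed
  expect_identical(bootstrap_auc_ci(y, pr, B = 100, seed = 9),
                   bootstrap_auc_ci(y, pr, B = 100, seed = 9))
})

test_that("cascade output respects its own gates end to end", {
  tab <- toy_feature_table(n = 80, p_signal = 3, p_noise = 10, delta = 2,
                           seed = 21)
  res <- run_selection_cascade(tab, n_perm = 200, seed = 5)
  expect_s3_class(res$model, "logistic_model")
  feats <- res$model$features
  expect_true(all(feats %in% res$selection$representatives$feature))
  expect_true(all(res$selection$representatives$p_value < 0.05))
  expect_true(all(feats %in% res$selection$filter$retained))
  expect_false(is.na(res$model$cutoff))
  # training AUC never materially below the best single retained feature
  y <- tab$label == "recurrent"
  auc_model <- localradiomics:::auc_rank(y, res$train_predictions)
  best_single <- max(res$selection$representatives$auc)
  expect_gte(auc_model, best_single - 0.02)
  # determinism under identical seed
  res2 <- run_selection_cascade(tab, n_perm = 200, seed = 5)
  expect_identical(res$model$coefficients, res2$model$coefficients)
  expect_identical(res$train_predictions, res2$train_predictions)
})

test_that("patient-level LOOCV runs the cascade per fold and reports folds", {
  tab <- toy_feature_table(n = 60, p_signal = 2, p_noise = 4, delta = 2.5,
                           seed = 31)
  cv <- loocv_patient(tab, n_perm = 100, seed = 2)
  expect_equal(cv$n_folds, length(unique(tab$patient_id)))
  expect_true(is.finite(cv$mean_auc))
  expect_gte(cv$mean_auc, 0.8)  # strong signal: folds should discriminate
  # label permutation destroys the signal
  set.seed(41)
  null_means <- vapply(1:3, function(s) {
    t2 <- tab
    t2[, feature_names()[1:6]] <-
      t2[sample(nrow(t2)), feature_names()[1:6]]
    loocv_patient(t2, n_perm = 50, seed = s)$mean_auc
  }, numeric(1))
  expect_lt(abs(mean(null_means) - 0.5), 0.2)
  expect_error(loocv_patient(tab[tab$label == "control", ]), "both")
})
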