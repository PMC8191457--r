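# Feature selection cascade: voxel-count correlation filter, PCA with
# parallel-analysis (Horn) component retention, Spearman grouping, and
# per-group univariate-AUC representatives.

#' Exclude features correlated with region size
#'
#' Features whose absolute Pearson correlation with the region voxel count
#' exceeds `r_max` are removed: for sub-volume analysis a feature that
#' tracks region size is confounded with geometry rather than texture.
#' Constant features are also removed (their correlation is undefined).
#'
#' @param table feature table from [build_feature_table()] (must contain
#'   `roi_voxel_count` and the feature columns).
#' @param r_max exclusion threshold on |r| (default 0.5).
#' @return List with `retained` (feature names), `excluded` (named numeric
#'   vector of r values for excluded features), `r` (all correlations).
#' @export
filter_voxel_correlation <- function(table, r_max = 0.5) {
  if (nrow(table) < 3) stop("need at least 3 rows")
  feats <- intersect(feature_names(), colnames(table))
  nv <- table$roi_voxel_count
  r <- vapply(feats, function(f) {
    x <- table[[f]]
    if (stats::sd(x) == 0 || stats::sd(nv) == 0) return(NA_real_)
    stats::cor(x, nv)
  }, numeric(1))
  excluded <- is.na(r) | abs(r) > r_max
  list(retained = feats[!excluded], excluded = r[excluded], r = r)
}

#' Number of principal components retained by parallel analysis
#'
#' Columns are z-scored and the eigenvalues of their correlation matrix are
#' compared with a null distribution obtained by independently permuting
#' each column (`n_perm` permuted tables). A component is retained while its
#' eigenvalue exceeds the `quantile` (default 95th percentile) of the
#' matched null eigenvalue; retention stops at the first failure so the
#' retained set is always the leading components.
#'
#' @param x numeric matrix or data.frame of features (rows = regions).
#' @param n_perm number of permuted null tables (default 1000).
#' @param quantile null eigenvalue quantile (default 0.95).
#' @param seed integer seed for the permutations.
#' @return List with `n_retained`, `loadings` (rotation matrix of retained
#'   components), `scores` (component scores of the input rows),
#'   `eigenvalues`, `null_quantiles`.
#' @export
horn_retained_components <- function(x, n_perm = 1000, quantile = 0.95,
                                     seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 3 || ncol(x) < 2) stop("need >= 3 rows and >= 2 features")
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("degenerate input: all features constant")
  x <- x[, sds > 0, drop = FALSE]
  z <- scale(x)
  n <- nrow(z); p <- ncol(z)
  ev <- function(m) {
    # eigenvalues of the correlation matrix of m (z-scored columns)
    e <- eigen(crossprod(m) / (n - 1), symmetric = TRUE, only.values = TRUE)
    pmax(e$values, 0)
  }
  obs <- eigen(crossprod(z) / (n - 1), symmetric = TRUE)
  obs_ev <- pmax(obs$values, 0)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  null_ev <- matrix(0, n_perm, p)
  for (b in seq_len(n_perm)) {
    zp <- apply(z, 2, sample)
    zp <- scale(zp)
    null_ev[b, ] <- ev(zp)
  }
  thr <- apply(null_ev, 2, stats::quantile, probs = quantile, type = 7)
  above <- obs_ev > thr
  k <- if (above[1]) which.min(c(above, FALSE)) - 1L else 0L
  scores <- z %*% obs$vectors
  list(n_retained = k,
       loadings = obs$vectors[, seq_len(max(k, 1)), drop = FALSE],
       scores = scores[, seq_len(max(k, 1)), drop = FALSE],
       eigenvalues = obs_ev, null_quantiles = thr,
       feature_names = colnames(x))
}

#' Group features by their strongest Spearman link to a component
#'
#' Each feature is assigned to the retained principal component with the
#' largest absolute Spearman correlation between the feature and the
#' component scores (ties go to the lower-index component). No feature is
#' ever orphaned.
#'
#' @param x feature matrix/data.frame (rows = regions).
#' @param scores matrix of retained component scores (columns = components).
#' @return Integer vector: component index per feature (named).
#' @export
group_by_component <- function(x, scores) {
  x <- as.matrix(x)
  scores <- as.matrix(scores)
  if (ncol(scores) < 1) stop("need at least 1 retained component")
  rho <- abs(stats::cor(x, scores, method = "spearman"))
  rho[is.na(rho)] <- -Inf
  grp <- apply(rho, 1, which.max)  # which.max takes the first (lowest) tie
  stats::setNames(as.integer(grp), colnames(x))
}

# Rank-based AUC of `pred` for binary labels (TRUE = positive); equivalent
# to the Mann-Whitney statistic with ties counted 1/2.
auc_rank <- function(labels, pred) {
  pos <- labels
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(pred)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Choose one representative feature per group
#'
#' Within each group, every feature is scored by a univariate logistic
#' regression of the binary label on the feature: the likelihood-ratio
#' p-value of the slope and the AUC of the fitted probabilities. The feature
#' with the largest AUC among those with p < `alpha` is the group
#' representative; a group with no feature below `alpha` contributes
#' nothing. (A likelihood-ratio rather than Wald test is used so that a
#' perfectly separating feature — whose Wald statistic degenerates — is
#' still recognized as significant.)
#'
#' @param x feature matrix/data.frame.
#' @param groups integer group index per feature (from
#'   [group_by_component()]).
#' @param labels logical or two-level vector; `TRUE`/`"recurrent"` is the
#'   positive class.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with one row per contributing group: `group`,
#'   `feature`, `auc`, `p_value`.
#' @export
select_representatives <- function(x, groups, labels, alpha = 0.05) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  x <- as.matrix(x)
  ll_null <- stable_logistic(matrix(numeric(0), length(y), 0), y)$loglik
  out <- list()
  for (g in sort(unique(groups))) {
    feats <- names(groups)[groups == g]
    stats_g <- lapply(feats, function(f) {
      xi <- x[, f]
      if (stats::sd(xi) == 0) return(NULL)
      fit <- stable_logistic(cbind(xi), y)
      lrt <- stats::pchisq(2 * pmax(fit$loglik - ll_null, 0), df = 1,
                           lower.tail = FALSE)
      list(feature = f, p = lrt, auc = auc_rank(y, fit$fitted))
    })
    stats_g <- Filter(Negate(is.null), stats_g)
    ok <- Filter(function(s) is.finite(s$p) && s$p < alpha, stats_g)
    if (length(ok) == 0) next
    aucs <- vapply(ok, function(s) s$auc, numeric(1))
    best <- ok[[which.max(aucs)]]
    out[[length(out) + 1]] <- data.frame(group = g, feature = best$feature,
                                         auc = best$auc, p_value = best$p)
  }
  if (length(out) == 0)
    return(data.frame(group = integer(0), feature = character(0),
                      auc = numeric(0), p_value = numeric(0)))
  do.call(rbind, out)
}

# Coerce labels to logical (positive class = TRUE / "recurrent" / second
# factor level / 1).
as_binary_label <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels == "recurrent"
}
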