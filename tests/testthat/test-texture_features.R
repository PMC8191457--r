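test_that("discretization anchors at the window and clamps to Ng", {
  a <- array(NA_real_, c(2, 2, 2))
  a[1:4] <- c(-20, -16, 180, 0)
  mv <- mv_from_array(a)
  d <- discretize(mv, 5)
  expect_equal(d$n_levels, 41)  # ceiling((180 - -20 + 1)/5)
  expect_equal(d$levels[1, 1, 1], 1L)   # lower edge
  expect_equal(d$levels[2, 1, 1], 1L)
  expect_equal(d$levels[1, 2, 1], 41L)  # upper edge clamps to Ng
  expect_equal(d$levels[2, 2, 1], 5L)
  expect_true(all(is.na(d$levels[, , 2])))
  expect_error(discretize(mv, 0), "bin_width")
})

test_that("GLCM matches hand enumeration on a 2x2x1 plane", {
  lev <- array(NA_integer_, c(2, 2, 1))
  lev[, , 1] <- c(1L, 1L, 1L, 2L)  # [[1,1],[1,2]] column-major
  d <- disc_from_levels(lev, 2)
  m <- glcm_matrix(d, c(1, 0, 0))
  # pairs along x: (1,1) and (1,2); symmetric counts
  expect_equal(m, matrix(c(2, 1, 1, 0), 2, 2))
  # constant region: single-cell matrix
  dc <- disc_from_levels(array(3L, c(3, 3, 3)), 5)
  fc <- glcm_features(dc, "merged")
  expect_equal(unname(fc["glcm_merged_joint_maximum"]), 1)
  expect_equal(unname(fc["glcm_merged_sum_entropy"]), 0)
  expect_equal(unname(fc["glcm_merged_cluster_shade"]), 0)
  # constant region: merged equals averaged
  fa <- glcm_features(dc, "averaged")
  expect_equal(unname(fa), unname(fc))
})

test_that("GLRLM matches hand enumeration and closed forms", {
  lev <- array(c(1L, 1L, 2L), c(3, 1, 1))
  d <- disc_from_levels(lev, 2)
  runs <- glrlm_runs(d, c(1, 0, 0))
  expect_equal(nrow(runs), 2)
  f <- glrlm_features_from_runs <- localradiomics:::glrlm_features_from_runs
  v <- f(runs, 2, 3)
  expect_equal(unname(v["gray_level_nonuniformity"]), 1)  # (1^2+1^2)/2
  # constant line: one run, GLN 1, run percentage 1/N
  dn <- disc_from_levels(array(2L, c(7, 1, 1)), 3)
  vn <- f(glrlm_runs(dn, c(1, 0, 0)), 3, 7)
  expect_equal(unname(vn["gray_level_nonuniformity"]), 1)
  expect_equal(unname(vn["run_percentage"]), 1 / 7)
  # all-distinct levels: every run length 1
  da <- disc_from_levels(array(1:5, c(5, 1, 1)), 5)
  va <- f(glrlm_runs(da, c(1, 0, 0)), 5, 5)
  expect_equal(unname(va["run_percentage"]), 1)
  expect_equal(unname(va["short_runs_emphasis"]), 1)
})

test_that("zones match the connected-component picture", {
  # 3x3x1 plane: ring of level 1 around center level 2
  lev <- array(1L, c(3, 3, 1)); lev[2, 2, 1] <- 2L
  z <- gl_zones(disc_from_levels(lev, 2))
  expect_equal(nrow(z), 2)
  expect_setequal(z$size, c(8, 1))
  # all border-adjacent in a 3x3x1 plane
  expect_true(all(z$distance == 1))
  # constant region: one zone, zero entropy/variance
  fc <- zone_features(disc_from_levels(array(2L, c(3, 3, 3)), 4))
  expect_equal(unname(fc["glszm_zone_size_entropy"]), 0)
  expect_equal(unname(fc["gldzm_gray_level_variance"]), 0)
  # single voxel: one zone of size 1 at distance 1
  lone <- array(NA_integer_, c(3, 3, 3)); lone[2, 2, 2] <- 1L
  z1 <- gl_zones(disc_from_levels(lone, 2))
  expect_equal(unlist(z1), c(level = 1, size = 1, distance = 1))
  # interior distance: 5x5x5 constant block has center distance 3
  z5 <- gl_zones(disc_from_levels(array(1L, c(5, 5, 5)), 1))
  expect_equal(z5$distance, 1)  # zone minimum is at the border
})

test_that("neighbourhood features match hand enumeration", {
  # NGLDM dependence of the center voxel of a constant 3x3x3 region is 26
  d <- disc_from_levels(array(1L, c(3, 3, 3)), 2)
  st <- localradiomics:::neighbour_stats(d)
  expect_equal(max(st$n_same), 26)
  fc <- neighbourhood_features(d)
  expect_equal(unname(fc["ngtdm_contrast"]), 0)
  expect_equal(unname(fc["ngtdm_complexity"]), 0)
  # checkerboard plane: neighbour means from brute force
  lev <- array(NA_integer_, c(3, 3, 1))
  lev[, , 1] <- ((outer(1:3, 1:3, `+`) %% 2) + 1L)
  or <- oracle_neighbours(lev)
  dd <- disc_from_levels(lev, 2)
  stc <- localradiomics:::neighbour_stats(dd)
  expect_equal(stc$sum_neigh / stc$n_neigh, or$mean_neigh)
  expect_equal(stc$n_same, or$n_same)
  lone <- array(NA_integer_, c(5, 5, 5)); lone[3, 3, 3] <- 1L
  expect_error(ngtdm_features(disc_from_levels(lone, 2)), "neighbor")
})

test_that("intensity statistics match direct arithmetic", {
  a <- array(NA_real_, c(3, 1, 1)); a[] <- c(1, 2, 3)
  mv <- mv_from_array(a, window = c(0, 10))
  f <- intensity_features(mv, discretize(mv, 1))
  expect_equal(unname(f["stat_median"]), 2)
  expect_equal(unname(f["stat_range"]), 2)
  expect_equal(unname(f["stat_mean"]), 2)
  expect_equal(unname(f["stat_variance"]), 2 / 3)  # population variance
  expect_equal(unname(f["stat_energy"]), 14)
  expect_equal(unname(f["stat_rms"]), sqrt(14 / 3))
  # percentiles follow the linear-interpolation rule
  x <- seq(10, 100, by = 10)
  mvx <- mv_from_array(array(x, c(10, 1, 1)), window = c(0, 200))
  fx <- intensity_features(mvx, discretize(mvx, 1))
  expect_equal(unname(fx["stat_p10"]), unname(quantile(x, 0.1, type = 7)))
  expect_equal(unname(fx["stat_p90"]), unname(quantile(x, 0.9, type = 7)))
  # constant region degeneracy
  mvc <- mv_from_array(array(7, c(3, 3, 3)), window = c(0, 10))
  fcst <- intensity_features(mvc, discretize(mvc, 1))
  expect_equal(unname(fcst[c("stat_variance", "stat_skewness",
                             "stat_kurtosis", "hist_range")]),
               c(0, 0, 0, 0))
})

test_that("feature vector has the full 161-name vocabulary and is deterministic", {
  expect_length(feature_names(), 161)
  expect_length(feature_names("intensity"), 25)
  expect_length(feature_names("texture"), 136)
  expect_length(feature_names("ngldm"), 17)
  # the feature names reported by bi-regional and local models exist
  expect_true(all(c("glrlm_averaged_gray_level_nonuniformity",
                    "glcm_merged_sum_entropy",
                    "glcm_averaged_cluster_shade",
                    "gldzm_gray_level_variance", "hist_median",
                    "glszm_zone_size_entropy",
                    "glcm_averaged_joint_maximum", "hist_range") %in%
                    feature_names()))
  set.seed(5)
  a <- array(rnorm(5^3, 60, 25), c(5, 5, 5))
  mv <- mv_from_array(a)
  f1 <- extract_feature_vector(mv)
  f2 <- extract_feature_vector(mv)
  expect_identical(f1, f2)
  expect_identical(names(f1), feature_names())
  expect_true(all(is.finite(f1)))
})

test_that("regions below 27 voxels are excluded, 27 accepted", {
  a <- array(NA_real_, c(4, 4, 4))
  a[seq_len(26)] <- rnorm(26, 50, 10)
  expect_error(extract_feature_vector(mv_from_array(a)),
               class = "region_too_small")
  a[27] <- 50
  expect_length(extract_feature_vector(mv_from_array(a)), 161)
})

test_that("features are translation invariant and blind to missing values", {
  set.seed(31)
  a <- array(rnorm(4^3, 70, 30), c(4, 4, 4))
  big1 <- array(NA_real_, c(9, 9, 9)); big1[1:4, 1:4, 1:4] <- a
  big2 <- array(NA_real_, c(9, 9, 9)); big2[5:8, 4:7, 6:9] <- a
  f1 <- extract_feature_vector(mv_from_array(big1))
  f2 <- extract_feature_vector(mv_from_array(big2))
  expect_equal(f1, f2, tolerance = 1e-12)
  # randomize what lies under the missing marker: nothing may change
  a2 <- a; a2[sample(64, 20)] <- NA
  mv <- mv_from_array(a2)
  f3 <- extract_feature_vector(mv)
  f4 <- extract_feature_vector(mv)  # NA content is NA; determinism
  expect_identical(f3, f4)
})

test_that("texture matrices match the brute-force oracle on random volumes", {
  set.seed(77)
  dirs <- oracle_dirs()
  for (trial in 1:40) {
    d <- random_disc(dm = sample(2:5, 3, replace = TRUE),
                     ng = sample(2:4, 1), p_missing = runif(1, 0, 0.4))
    if (!any(!is.na(d$levels))) next
    for (dir in dirs[sample(13, 4)]) {
      expect_equal(glcm_matrix(d, dir), oracle_glcm(d$levels, d$n_levels, dir))
      ro <- oracle_runs(d$levels, dir)
      ri <- glrlm_runs(d, dir)
      expect_equal(ro[order(ro$level, ro$length), ],
                   ri[order(ri$level, ri$length), ], ignore_attr = TRUE)
    }
    zo <- oracle_zones(d$levels)
    zi <- gl_zones(d)
    expect_equal(zo[order(zo$level, zo$size, zo$distance), ],
                 zi[order(zi$level, zi$size, zi$distance), ],
                 ignore_attr = TRUE)
    on <- oracle_neighbours(d$levels)
    st <- localradiomics:::neighbour_stats(d)
    expect_equal(st$level, on$level)
    expect_equal(st$n_neigh, on$n_neigh)
    expect_equal(st$n_same, on$n_same)
  }
})

test_that("matrix-based probability distributions sum to one", {
  set.seed(88)
  for (i in 1:20) {
    d <- random_disc(dm = c(4, 4, 4), ng = 4, p_missing = 0.2)
    n_valid <- sum(!is.na(d$levels))
    if (n_valid < 8) next
    m <- glcm_matrix(d, c(1, 0, 0))
    if (sum(m) > 0) expect_equal(sum(m / sum(m)), 1, tolerance = 1e-9)
    f <- extract_feature_vector(
      mv_from_array(array(rnorm(6^3, 60, 20), c(6, 6, 6))))
    expect_true(all(f[grep("entropy", names(f))] >= 0))
    unif <- f[grep("nonuniformity_normalised|angular_second_moment|hist_uniformity",
                   names(f))]
    expect_true(all(unif > 0 & unif <= 1))
  }
})
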