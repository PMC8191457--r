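# Canonical feature vocabulary: 25 intensity + 136 texture features.
# Order is fixed; feature tables and vectors always use these names.

.stat_names <- c(
  "stat_mean", "stat_variance", "stat_skewness", "stat_kurtosis",
  "stat_median", "stat_minimum", "stat_p10", "stat_p90", "stat_maximum",
  "stat_iqr", "stat_range", "stat_mean_abs_deviation",
  "stat_robust_mean_abs_deviation", "stat_median_abs_deviation",
  "stat_cov", "stat_quartile_coeff_dispersion", "stat_energy", "stat_rms")

.hist_names <- c(
  "hist_mean", "hist_variance", "hist_median", "hist_range",
  "hist_entropy", "hist_uniformity", "hist_mode")

.glcm_base <- c(
  "joint_maximum", "joint_average", "joint_variance", "joint_entropy",
  "difference_average", "difference_variance", "difference_entropy",
  "sum_average", "sum_variance", "sum_entropy",
  "angular_second_moment", "contrast", "dissimilarity",
  "inverse_difference", "inverse_difference_normalised",
  "inverse_difference_moment", "inverse_difference_moment_normalised",
  "inverse_variance", "correlation", "autocorrelation",
  "cluster_tendency", "cluster_shade", "cluster_prominence",
  "information_correlation_1", "information_correlation_2")

.glrlm_base <- c(
  "short_runs_emphasis", "long_runs_emphasis",
  "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
  "short_run_low_gray_level_emphasis", "short_run_high_gray_level_emphasis",
  "long_run_low_gray_level_emphasis", "long_run_high_gray_level_emphasis",
  "gray_level_nonuniformity", "gray_level_nonuniformity_normalised",
  "run_length_nonuniformity", "run_length_nonuniformity_normalised",
  "run_percentage", "gray_level_variance", "run_length_variance",
  "run_entropy")

.glszm_names <- paste0("glszm_", c(
  "small_zone_emphasis", "large_zone_emphasis",
  "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
  "small_zone_low_gray_level_emphasis", "small_zone_high_gray_level_emphasis",
  "large_zone_low_gray_level_emphasis", "large_zone_high_gray_level_emphasis",
  "gray_level_nonuniformity", "gray_level_nonuniformity_normalised",
  "zone_size_nonuniformity", "zone_size_nonuniformity_normalised",
  "zone_percentage", "gray_level_variance", "zone_size_variance",
  "zone_size_entropy"))

.gldzm_names <- paste0("gldzm_", c(
  "small_distance_emphasis", "large_distance_emphasis",
  "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
  "small_distance_low_gray_level_emphasis",
  "small_distance_high_gray_level_emphasis",
  "large_distance_low_gray_level_emphasis",
  "large_distance_high_gray_level_emphasis",
  "gray_level_nonuniformity", "gray_level_nonuniformity_normalised",
  "zone_distance_nonuniformity", "zone_distance_nonuniformity_normalised",
  "zone_percentage", "gray_level_variance", "zone_distance_variance",
  "zone_distance_entropy"))

.ngtdm_names <- paste0("ngtdm_", c(
  "coarseness", "contrast", "busyness", "complexity", "strength"))

.ngldm_names <- paste0("ngldm_", c(
  "low_dependence_emphasis", "high_dependence_emphasis",
  "low_gray_level_count_emphasis", "high_gray_level_count_emphasis",
  "low_dependence_low_gray_level_emphasis",
  "low_dependence_high_gray_level_emphasis",
  "high_dependence_low_gray_level_emphasis",
  "high_dependence_high_gray_level_emphasis",
  "gray_level_nonuniformity", "gray_level_nonuniformity_normalised",
  "dependence_count_nonuniformity",
  "dependence_count_nonuniformity_normalised",
  "dependence_count_percentage", "gray_level_variance",
  "dependence_count_variance", "dependence_count_entropy",
  "dependence_count_energy"))

#' Canonical feature names
#'
#' Returns the fixed 161-name vocabulary: 25 intensity features (18 raw-HU
#' statistics + 7 discretized-histogram features) and 136 texture features
#' (25 GLCM x averaged/merged, 16 GLRLM x averaged/merged, 16 GLSZM,
#' 16 GLDZM, 5 NGTDM, 17 NGLDM). Feature tables and vectors produced by this
#' package use exactly these names, in this order.
#'
#' @param family optional subset: one of `"intensity"`, `"glcm"`, `"glrlm"`,
#'   `"glszm"`, `"gldzm"`, `"ngtdm"`, `"ngldm"`, `"texture"`, `"all"`.
#' @return Character vector of feature names.
#' @examples
#' length(feature_names())          # 161
#' length(feature_names("texture")) # 136
#' @export
feature_names <- function(family = c("all", "intensity", "texture", "glcm",
                                     "glrlm", "glszm", "gldzm", "ngtdm",
                                     "ngldm")) {
  family <- match.arg(family)
  intensity <- c(.stat_names, .hist_names)
  glcm <- c(paste0("glcm_averaged_", .glcm_base),
            paste0("glcm_merged_", .glcm_base))
  glrlm <- c(paste0("glrlm_averaged_", .glrlm_base),
             paste0("glrlm_merged_", .glrlm_base))
  texture <- c(glcm, glrlm, .glszm_names, .gldzm_names, .ngtdm_names,
               .ngldm_names)
  switch(family,
         all = c(intensity, texture),
         intensity = intensity,
         texture = texture,
         glcm = glcm,
         glrlm = glrlm,
         glszm = .glszm_names,
         gldzm = .gldzm_names,
         ngtdm = .ngtdm_names,
         ngldm = .ngldm_names)
}
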