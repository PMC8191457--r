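# Small in-code fixtures shared across tests.

# Masked volume directly from an array (NA = missing), bypassing I/O.
mv_from_array <- function(a, window = c(-20, 180), spacing = c(1, 1, 1)) {
  structure(list(data = a, spacing = spacing, origin = c(0, 0, 0),
                 window = window, roi_voxel_count = sum(!is.na(a))),
            class = "masked_volume")
}

# Discretized volume directly from a level array.
disc_from_levels <- function(lev, ng) {
  structure(list(levels = lev, n_levels = as.integer(ng), bin_width = 1,
                 window = c(0, ng)), class = "discretized_volume")
}

# Random ROI mask on an n^3 grid with roughly p foreground.
random_mask <- function(n = 8, p = 0.4) {
  roi_mask(array(stats::runif(n^3) < p, c(n, n, n)))
}

# Feature table with controlled signal for cascade tests: `signal` features
# shifted by `delta` between classes, the rest pure noise.
toy_feature_table <- function(n = 60, p_signal = 2, p_noise = 6, delta = 1.5,
                              seed = 1) {
  set.seed(seed)
  label <- rep(c("control", "recurrent"), length.out = n)
  shift <- ifelse(label == "recurrent", delta, 0)
  x <- cbind(
    matrix(stats::rnorm(n * p_signal) + shift, n, p_signal),
    matrix(stats::rnorm(n * p_noise), n, p_noise))
  colnames(x) <- feature_names()[seq_len(p_signal + p_noise)]
  data.frame(patient_id = sprintf("pt%02d", rep(seq_len(n / 2), each = 2)),
             region_id = seq_len(n), label = label,
             roi_voxel_count = round(stats::runif(n, 30, 300)),
             x, check.names = FALSE)
}
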