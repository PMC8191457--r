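#' Discretize a masked volume into gray levels
#'
#' Fixed-bin-width discretization anchored at the lower edge of the HU
#' window: `level(x) = floor((x - low)/bin_width) + 1`, clamped to
#' `[1, Ng]` with `Ng = ceiling((high - low + 1)/bin_width)`. `Ng` is a
#' function of the window alone, never of the observed data, so levels are
#' comparable across regions and patients — a requirement for local
#' (sub-volume) analysis. Missing voxels stay missing.
#'
#' @param mv a `masked_volume` from [apply_hu_window()].
#' @param bin_width bin width in HU (default 5, giving Ng = 41 for the
#'   default -20..180 window).
#' @return A `discretized_volume`: list with `levels` (integer array, NA for
#'   missing), `n_levels`, `bin_width`, `window`.
#' @export
discretize <- function(mv, bin_width = 5) {
  if (!inherits(mv, "masked_volume")) stop("'mv' must be a masked_volume")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("'bin_width' must be a single positive number")
  low <- mv$window[1]; high <- mv$window[2]
  ng <- as.integer(ceiling((high - low + 1) / bin_width))
  lev <- floor((mv$data - low) / bin_width) + 1
  lev <- pmin(pmax(lev, 1), ng)
  structure(list(levels = array(as.integer(lev), dim(mv$data)),
                 n_levels = ng, bin_width = bin_width, window = mv$window),
            class = "discretized_volume")
}

#' @export
print.discretized_volume <- function(x, ...) {
  cat(sprintf("discretized_volume: %s voxels, Ng = %d (bin width %g HU)\n",
              paste(dim(x$levels), collapse = "x"), x$n_levels, x$bin_width))
  invisible(x)
}
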