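#' Haemodynamic response function parameters
#'
#' Difference-of-gammas (double-gamma) HRF parameterisation. The human preset
#' reproduces the canonical shape used by standard fMRI software (response
#' peaking around 5 s with a late undershoot). The dog preset keeps the same
#' family but moves the response peak 2.5 s earlier, reflecting the faster
#' BOLD peak reported for dogs; it is a configurable default, not a fixed
#' physiological constant.
#'
#' @param species "human" or "dog" preset.
#' @param peak_delay,undershoot_delay gamma delays in seconds (delay =
#'   shape x dispersion).
#' @param peak_dispersion,undershoot_dispersion gamma dispersions in seconds.
#' @param undershoot_ratio positive scaling of the undershoot gamma.
#' @param kernel_length kernel support in seconds.
#' @param dt sampling interval of the kernel in seconds.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(species = c("human", "dog"),
                       peak_delay = NULL,
                       undershoot_delay = NULL,
                       peak_dispersion = 1,
                       undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6,
                       kernel_length = 32,
                       dt = 1 / 16) {
  species <- match.arg(species)
  if (is.null(peak_delay)) peak_delay <- if (species == "dog") 3.5 else 6
  if (is.null(undershoot_delay))
    undershoot_delay <- if (species == "dog") 13.5 else 16
  p <- list(species = species,
            peak_delay = peak_delay,
            undershoot_delay = undershoot_delay,
            peak_dispersion = peak_dispersion,
            undershoot_dispersion = undershoot_dispersion,
            undershoot_ratio = undershoot_ratio,
            kernel_length = kernel_length,
            dt = dt)
  num <- unlist(p[-1])
  if (any(!is.finite(num)) || any(num <= 0))
    stopf("all HRF parameters must be positive and finite")
  structure(p, class = "hrf_params")
}

#' Sample a double-gamma HRF kernel
#'
#' The kernel is the difference of two gamma densities (response minus
#' ratio-scaled undershoot), sampled on a regular grid and normalised to
#' peak 1. With shape > 1 the kernel is exactly 0 at t = 0.
#'
#' @param params an [hrf_params()] object.
#' @param dt optional override of the sampling interval (s).
#' @return Numeric vector of kernel values at `seq(0, kernel_length, by = dt)`,
#'   with the time grid as attribute `time`.
#' @export
hrf_kernel <- function(params = hrf_params("human"), dt = NULL) {
  if (!inherits(params, "hrf_params")) stopf("`params` must be hrf_params")
  dt <- dt %||% params$dt
  if (!is.finite(dt) || dt <= 0) stopf("`dt` must be positive")
  t <- seq(0, params$kernel_length, by = dt)
  shape1 <- params$peak_delay / params$peak_dispersion
  shape2 <- params$undershoot_delay / params$undershoot_dispersion
  k <- dgamma(t, shape = shape1, scale = params$peak_dispersion) -
    params$undershoot_ratio *
      dgamma(t, shape = shape2, scale = params$undershoot_dispersion)
  k <- k / max(k)
  attr(k, "time") <- t
  k
}

## Time (s) at which the sampled kernel peaks.
hrf_peak_time <- function(params, dt = 0.01) {
  k <- hrf_kernel(params, dt = dt)
  attr(k, "time")[which.max(k)]
}
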