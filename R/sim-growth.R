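#' Simulate an exponential growth curve with multiplicative noise
#'
#' `OD(t) = od0 * exp(rate * t) * exp(e_t)` with
#' `e_t ~ Normal(0, noise_sd^2)` independent across time points.
#'
#' @param rate exponential growth rate per hour (any real number).
#' @param od0 initial optical density (> 0).
#' @param times sampling times in hours, strictly increasing.
#' @param noise_sd log-scale standard deviation of the multiplicative
#'   noise (>= 0; 0 gives an exact exponential).
#' @param seed integer seed.
#' @return object of class `growth_curve`: data.frame with columns
#'   `time_h` and `od600`, plus attributes `rate` (truth) and `od0`.
#' @export
simulate_growth_curve <- function(rate, od0, times, noise_sd = 0,
                                  seed = 1L) {
  if (od0 <= 0) stop("od0 must be positive")
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  eps <- if (noise_sd > 0) local_rng(seed)$rnorm(length(times), 0, noise_sd)
         else rep(0, length(times))
  curve <- data.frame(time_h = times,
                      od600 = od0 * exp(rate * times) * exp(eps))
  attr(curve, "rate") <- rate
  attr(curve, "od0") <- od0
  class(curve) <- c("growth_curve", "data.frame")
  curve
}
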