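#' Exponential growth rate from an OD600 time series
#'
#' The growth rate is the OLS regression slope of the natural logarithm
#' of OD600 on time, the standard log-linear estimate for exponential
#' growth.
#'
#' @param curve a `growth_curve` from [simulate_growth_curve()] or any
#'   data.frame with columns `time_h` and `od600`.
#' @param t_min optional lower time bound; earlier samples are dropped
#'   (e.g. to exclude a post-induction lag).
#' @return object of class `growth_rate`: list with `rate` (per hour),
#'   `rate_se`, `n`, `r_squared`, `p`.
#' @export
estimate_growth_rate <- function(curve, t_min = NULL) {
  stopifnot(all(c("time_h", "od600") %in% names(curve)))
  t <- curve$time_h
  od <- curve$od600
  if (!is.null(t_min)) {
    keep <- t >= t_min
    t <- t[keep]
    od <- od[keep]
  }
  if (length(t) < 3L) stop("need at least 3 samples")
  if (any(od <= 0)) stop("od600 values must be positive")
  if (length(unique(t)) == 1L) stop("constant time vector")
  fit <- regression_slope(t, log(od))
  structure(
    list(rate = fit$slope, rate_se = fit$se, n = fit$n,
         r_squared = fit$r_squared, p = fit$p),
    class = "growth_rate"
  )
}

#' @export
print.growth_rate <- function(x, ...) {
  cat(sprintf("growth rate: %.4f / h (SE %.4f, n = %d, R^2 = %.3f)\n",
              x$rate, x$rate_se, x$n, x$r_squared))
  invisible(x)
}

#' Relative growth cost as percent slowdown
#'
#' `100 * (reference_rate - rate) / reference_rate`: positive when the
#' strain grows slower than the reference, negative when it grows faster.
#'
#' @param rate growth rate of the strain of interest (per hour).
#' @param reference_rate growth rate of the reference strain (> 0).
#' @export
relative_growth_cost <- function(rate, reference_rate) {
  if (any(reference_rate <= 0)) stop("reference_rate must be positive")
  100 * (reference_rate - rate) / reference_rate
}

#' Compare replicate growth rates across strains
#'
#' Per-strain mean rate, SEM (`sd / sqrt(n)`; `NA` with a flag for
#' single-replicate strains), mean relative cost against a reference
#' strain, and pairwise two-sided Mann-Whitney tests between strains.
#'
#' @param rates data.frame with columns `strain` and `rate` (one row per
#'   replicate).
#' @param reference strain id used as the cost reference; default the
#'   first strain. The reference cost baseline is that strain's mean rate.
#' @return list with `summary` (per-strain data.frame: `strain`, `n`,
#'   `mean_rate`, `sem`, `mean_cost_pct`) and `tests` (pairwise
#'   data.frame: `strain_a`, `strain_b`, `U`, `p`).
#' @export
compare_conditions <- function(rates, reference = NULL) {
  stopifnot(all(c("strain", "rate") %in% names(rates)))
  strains <- unique(rates$strain)
  if (length(strains) < 2L) stop("need at least 2 strains")
  by_strain <- split(rates$rate, factor(rates$strain, levels = strains))
  if (is.null(reference)) reference <- strains[1]
  if (!reference %in% strains) stop("unknown reference strain: ", reference)
  ref_rate <- mean(by_strain[[reference]])
  summary_df <- data.frame(
    strain = strains,
    n = vapply(by_strain, length, integer(1)),
    mean_rate = vapply(by_strain, mean, numeric(1)),
    sem = vapply(by_strain, function(v) {
      if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  summary_df$mean_cost_pct <- relative_growth_cost(summary_df$mean_rate,
                                                   ref_rate)
  if (any(summary_df$n < 2L)) {
    warning("strain(s) with a single replicate: SEM undefined: ",
            paste(summary_df$strain[summary_df$n < 2L], collapse = ", "))
  }
  combos <- utils::combn(strains, 2L)
  tests <- apply(combos, 2L, function(pr) {
    mw <- mann_whitney_u(by_strain[[pr[1]]], by_strain[[pr[2]]])
    data.frame(strain_a = pr[1], strain_b = pr[2], U = mw$statistic,
               p = mw$p, stringsAsFactors = FALSE)
  })
  list(summary = summary_df, tests = do.call(rbind, tests))
}

#' Synthesis rates from band-intensity time series
#'
#' Per-strain OLS slope of band intensity on time (linear scale, no log)
#' and pairwise Welch t tests of slope equality between strains — the
#' gel-quantification analysis of relative protein synthesis rates.
#'
#' @param bands data.frame with columns `strain`, `time`, `intensity`
#'   (>= 3 time points per strain).
#' @return list with `slopes` (per-strain data.frame: `strain`, `slope`,
#'   `se`, `n`) and `tests` (pairwise data.frame: `strain_a`, `strain_b`,
#'   `t`, `df`, `p`).
#' @export
synthesis_rate <- function(bands) {
  stopifnot(all(c("strain", "time", "intensity") %in% names(bands)))
  strains <- unique(bands$strain)
  fits <- lapply(strains, function(s) {
    d <- bands[bands$strain == s, ]
    regression_slope(d$time, d$intensity)
  })
  names(fits) <- strains
  slopes <- data.frame(
    strain = strains,
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    n = vapply(fits, `[[`, integer(1), "n"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tests <- NULL
  if (length(strains) >= 2L) {
    combos <- utils::combn(strains, 2L)
    tests <- do.call(rbind, apply(combos, 2L, function(pr) {
      st <- slope_difference_test(fits[[pr[1]]], fits[[pr[2]]])
      data.frame(strain_a = pr[1], strain_b = pr[2], t = st$t, df = st$df,
                 p = st$p, stringsAsFactors = FALSE)
    }))
  }
  list(slopes = slopes, tests = tests)
}
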