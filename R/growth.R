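#' Per-interval absolute growth rate
#'
#' Classical plant-growth-analysis definition: difference between
#' consecutive time points divided by the sampling interval,
#' `AGR_i = (x_i - x_{i-1}) / interval`. The standard protocol measures every
#' 3 days, nine times. Output names follow the trait-table convention
#' (`AGR<trait><i>`), with the index origin configurable because CT trait
#' columns are labelled i = 2..9 and RGB ones i = 1..8 for the same
#' consecutive intervals.
#'
#' @param x Numeric trait values at consecutive time points (length >= 2);
#'   `NA`s propagate to the affected intervals.
#' @param interval Days between time points.
#' @param trait Optional trait abbreviation used to name the result.
#' @param index_origin Label of the first interval (2 for CT traits,
#'   1 for RGB traits).
#' @return Named numeric vector of `length(x) - 1` rates per day.
#' @export
absolute_growth_rate <- function(x, interval = 3, trait = NULL,
                                 index_origin = 2) {
  if (length(x) < 2) stop("need at least two time points")
  r <- diff(x) / interval
  names(r) <- paste0(if (is.null(trait)) "AGR" else paste0("AGR", trait),
                     seq_along(r) + index_origin - 1)
  r
}

#' Per-interval relative growth rate
#'
#' Log-difference per day, `RGR_i = (ln x_i - ln x_{i-1}) / interval`; the
#' RGR of an exponential trajectory equals its rate constant at every
#' interval. Non-positive values give missing rates with a warning.
#'
#' @inheritParams absolute_growth_rate
#' @return Named numeric vector of `length(x) - 1` rates per day.
#' @export
relative_growth_rate <- function(x, interval = 3, trait = NULL,
                                 index_origin = 2) {
  if (length(x) < 2) stop("need at least two time points")
  bad <- !is.na(x) & x <= 0
  if (any(bad)) {
    warning("non-positive values; affected relative growth rates are missing")
    x[bad] <- NA
  }
  r <- diff(log(x)) / interval
  names(r) <- paste0(if (is.null(trait)) "RGR" else paste0("RGR", trait),
                     seq_along(r) + index_origin - 1)
  r
}

#' Mean absolute percentage error
#'
#' `MAPE = 100/n * sum(|x_a - x_m| / x_m)` between automatic and manual
#' (reference) measurements; undefined when any reference value is zero.
#'
#' @param auto,manual Equal-length numeric vectors.
#' @return Percent.
#' @export
mape <- function(auto, manual) {
  if (length(auto) != length(manual)) stop("lengths differ")
  if (length(auto) == 0) stop("empty input")
  if (any(manual == 0)) stop("MAPE undefined for zero reference values")
  mean(abs(auto - manual) / abs(manual)) * 100
}

#' Root mean square error
#'
#' @inheritParams mape
#' @return Same units as the inputs.
#' @export
rmse <- function(auto, manual) {
  if (length(auto) != length(manual)) stop("lengths differ")
  if (length(auto) == 0) stop("empty input")
  sqrt(mean((auto - manual)^2))
}

#' Population SD of the absolute percentage errors
#'
#' The dispersion companion to [mape()]: the population standard deviation of
#' the per-point absolute percentage errors.
#'
#' @inheritParams mape
#' @return Percent.
#' @export
sd_ape <- function(auto, manual) {
  if (length(auto) != length(manual)) stop("lengths differ")
  if (any(manual == 0)) stop("undefined for zero reference values")
  sd_pop(abs(auto - manual) / abs(manual) * 100)
}

#' Tiller senescence
#'
#' Fraction of late-stage tillers that never boot:
#' `(TN_9 - TN_effective) / TN_9`, where `TN_9` is the tiller count at the
#' ninth (late tillering) time point and `TN_effective` the effective
#' (booted, hollow-pith) tiller count at maturity.
#'
#' @param tn9 Tiller number at time point 9; must be > 0.
#' @param tn_effective Effective tiller number at maturity.
#' @return List of class `"senescence_result"`: `TN_9`, `TN_effective`,
#'   `senescence`. A negative senescence (more effective tillers than
#'   late-stage tillers, e.g. from a counting error) is allowed but flagged
#'   with a warning.
#' @export
tiller_senescence <- function(tn9, tn_effective) {
  if (tn9 <= 0) stop("TN_9 must be positive")
  if (tn_effective > tn9)
    warning("TN_effective exceeds TN_9; senescence is negative")
  structure(list(TN_9 = tn9, TN_effective = tn_effective,
                 senescence = (tn9 - tn_effective) / tn9),
            class = "senescence_result")
}

#' @export
print.senescence_result <- function(x, ...) {
  cat(sprintf("Tiller senescence: (%g - %g) / %g = %.3f\n",
              x$TN_9, x$TN_effective, x$TN_9, x$senescence))
  invisible(x)
}
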