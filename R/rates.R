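# Declining exponential approximation of life expectancy (DEALE):
# survival figures -> constant instantaneous rates -> annual probabilities.
# The base-case table already reports annual probabilities, so the cohort
# engine consumes those directly; these helpers exist for provenance and
# for re-deriving probabilities from other studies' survival figures.

#' Instantaneous annual rate from a median survival time
#'
#' Under a constant-hazard (exponential) survival model, survival is 0.5 at
#' the median, so the rate is \eqn{\ln 2 / m}.
#'
#' @param median_years Median survival (or time-to-event) in years; > 0.
#' @return Instantaneous rate per year.
#' @export
#' @examples
#' rate_from_median(1)    # log(2)
#' rate_to_annual_prob(rate_from_median(10))
rate_from_median <- function(median_years) {
  if (any(!is.finite(median_years)) || any(median_years <= 0)) {
    rlang::abort("median_years must be positive and finite")
  }
  log(2) / median_years
}

#' Instantaneous annual rate from a cumulative surviving fraction
#'
#' Converts "fraction s event-free at h years" into the constant rate
#' \eqn{-\ln(s) / h} of the exponential model.
#'
#' @param surviving_fraction Event-free fraction at the horizon; in (0, 1].
#' @param horizon_years Length of the observation window in years; > 0.
#' @return Instantaneous rate per year.
#' @export
rate_from_cumulative <- function(surviving_fraction, horizon_years) {
  if (any(!is.finite(surviving_fraction)) || any(surviving_fraction <= 0) ||
      any(surviving_fraction > 1)) {
    rlang::abort("surviving_fraction must be in (0, 1]")
  }
  if (any(!is.finite(horizon_years)) || any(horizon_years <= 0)) {
    rlang::abort("horizon_years must be positive and finite")
  }
  -log(surviving_fraction) / horizon_years
}

#' Convert a constant annual rate to a per-cycle probability
#'
#' The one-cycle transition probability of an exponential process with
#' rate r is \eqn{1 - e^{-r}}.
#'
#' @param rate Instantaneous rate per year; >= 0.
#' @return Annual transition probability in [0, 1).
#' @export
rate_to_annual_prob <- function(rate) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    rlang::abort("rate must be non-negative and finite")
  }
  1 - exp(-rate)
}

#' Convert a per-cycle probability to a constant annual rate
#'
#' Inverse of [rate_to_annual_prob()]: \eqn{-\ln(1 - p)}.
#'
#' @param prob Annual probability; in [0, 1).
#' @return Instantaneous rate per year.
#' @export
prob_to_rate <- function(prob) {
  if (any(!is.finite(prob)) || any(prob < 0) || any(prob >= 1)) {
    rlang::abort("prob must be in [0, 1)")
  }
  -log(1 - prob)
}
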