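#' Potential daily body-weight growth rate (Gompertz)
#'
#' The potential growth rate of an adequately fed animal follows a
#' parameterized Gompertz curve,
#' \deqn{dBW/dt = \mu_0 \, BW \, \frac{\ln(BW_f/BW)}{\ln(BW_f/BW_0)},}
#' where \eqn{BW_0} is the birth weight and \eqn{BW_f} the mature weight,
#' taken as 90% of the genetic maximum attainable weight because cattle
#' under (sub-)tropical feeding rarely reach their genetic final weight.
#' The rate is capped at `breed$max_daily_gain` (default 1.2 kg/day) to
#' avoid unrealistic potential gains, and is zero at or above \eqn{BW_f}.
#'
#' @param bw Current body weight (kg); vectorized.
#' @param breed A [breed_parameters()] object.
#' @return Potential growth rate (kg/day), non-negative.
#' @examples
#' b <- breed_parameters("x", "crossbred", "female", 30, 500, 280,
#'                       peak_milk_yield = 20, peak_month = 2,
#'                       lactation_length = 10, milk_fat = 46.3)
#' potential_growth_rate(200, b)
#' @export
potential_growth_rate <- function(bw, breed) {
  if (any(bw <= 0)) stop_domain("body weight must be positive")
  bwf <- mature_weight(breed)
  bw_eff <- pmin(bw, bwf)
  rate <- breed$gompertz_mu0 * bw_eff *
    log(bwf / bw_eff) / log(bwf / breed$birth_weight)
  pmin(pmax(rate, 0), breed$max_daily_gain)
}

mature_weight <- function(breed) 0.9 * breed$max_attainable_weight

## Closed-form Gompertz body-weight trajectory from birth toward an
## asymptote `bw_asym`, with the same mu0 convention as the rate equation:
## the decay constant is mu0 / ln(bw_asym / bw0).
gompertz_weight_at_age <- function(age_years, bw0, bw_asym, mu0) {
  t_days <- age_years * 365.25
  k <- mu0 / log(bw_asym / bw0)
  bw_asym * (bw0 / bw_asym)^exp(-k * t_days)
}

#' Body-weight envelope of a breed
#'
#' The condition index locates an animal's current weight between a
#' breed-and-age-specific minimum and maximum body weight.  Both envelope
#' trajectories are generated with the same Gompertz form as the potential
#' growth curve (same birth weight, same \eqn{\mu_0}): the minimum
#' trajectory grows toward `min_mature_weight` and the maximum toward 90%
#' of `max_attainable_weight`, keeping the envelope internally consistent
#' with the growth model.
#'
#' @param breed A [breed_parameters()] object.
#' @return An object of class `growth_envelope`: a list with vectorized
#'   functions `bw_min_at_age(age)` and `bw_max_at_age(age)` (age in years,
#'   result in kg) and the scalar `final_weight` (kg).
#' @examples
#' b <- breed_parameters("x", "crossbred", "female", 30, 500, 280,
#'                       peak_milk_yield = 20, peak_month = 2,
#'                       lactation_length = 10, milk_fat = 46.3)
#' env <- growth_envelope(b)
#' env$bw_max_at_age(5.2)
#' @export
growth_envelope <- function(breed) {
  bw0 <- breed$birth_weight
  mu0 <- breed$gompertz_mu0
  lo <- breed$min_mature_weight
  hi <- mature_weight(breed)
  if (lo >= hi) {
    stop_invalid(sprintf(
      "degenerate envelope: min mature weight (%g) >= 0.9 x max attainable (%g)",
      lo, hi))
  }
  structure(list(
    bw_min_at_age = function(age) gompertz_weight_at_age(age, bw0, lo, mu0),
    bw_max_at_age = function(age) gompertz_weight_at_age(age, bw0, hi, mu0),
    final_weight = hi
  ), class = "growth_envelope")
}

#' Body-weight condition index
#'
#' Position of the current body weight between the age-specific minimum and
#' maximum weights of the breed envelope,
#' \deqn{(BW_t - BW_{min,t}) / (BW_{max,t} - BW_{min,t}),}
#' clamped to \[0, 1\].  The index down-scales both the potential milk
#' yield and the predicted voluntary dry-matter intake, so that thin
#' animals eat and produce below their genetic potential.
#'
#' @param bw Body weight (kg); vectorized with `age`.
#' @param age Age (years).
#' @param envelope A [growth_envelope()].
#' @return Condition index in \[0, 1\] (kg/kg).
#' @export
condition_index <- function(bw, age, envelope) {
  lo <- envelope$bw_min_at_age(age)
  hi <- envelope$bw_max_at_age(age)
  if (any(hi - lo <= sqrt(.Machine$double.eps))) {
    stop_domain("degenerate envelope: BW_max equals BW_min at this age")
  }
  pmin(pmax((bw - lo) / (hi - lo), 0), 1)
}
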