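#' Potential milk yield in a given month of lactation
#'
#' A two-parameter lactation curve driven only by the peak milk yield and
#' the month `T` in which the peak occurs:
#' \deqn{y(n) = \frac{n}{a\,e^{kn}}, \quad a = \frac{1}{peak \cdot (1/T) \cdot e},
#'   \quad k = 1/T.}
#' With this parameterization the curve attains its maximum, equal to the
#' peak yield, exactly at month \eqn{n = T}.  Months outside the lactation
#' (\eqn{n \le 0} or \eqn{n >} lactation length) return 0.
#'
#' This is the unmodified genetic potential; during simulation it is
#' multiplied by the body-weight condition index (and an age factor,
#' currently fixed at 1) before entering the requirement calculations.
#'
#' @param n Month of lactation (integer-valued; first month is 1);
#'   vectorized.
#' @param breed A [breed_parameters()] object supplying `peak_milk_yield`,
#'   `peak_month` and `lactation_length`.
#' @return Potential milk yield (kg/animal/day).
#' @examples
#' b <- breed_parameters("x", "crossbred", "female", 30, 500, 280,
#'                       peak_milk_yield = 20, peak_month = 2,
#'                       lactation_length = 10, milk_fat = 46.3)
#' potential_milk_yield(1:10, b)
#' @export
potential_milk_yield <- function(n, breed) {
  peak <- breed$peak_milk_yield
  T_pk <- breed$peak_month
  a <- 1 / (peak * (1 / T_pk) * exp(1))
  k <- 1 / T_pk
  y <- n / (a * exp(k * n))
  y[n <= 0 | n > breed$lactation_length] <- 0
  y
}

#' Stage of lactation
#'
#' Early lactation is the first three months after calving (the phase in
#' which body reserves may be mobilized for milk), late lactation the last
#' three months of the lactation length, and mid lactation everything in
#' between.  Month 0 means the animal is dry.
#'
#' @param n Month of lactation (0 = dry); vectorized.
#' @param lactation_length Lactation length (months).
#' @return Factor with levels `early`, `mid`, `late`, `dry`.
#' @examples
#' lactation_stage(0:10, 10)
#' @export
lactation_stage <- function(n, lactation_length) {
  if (any(n < 0 | n > lactation_length)) {
    stop_domain("lactation month outside [0, lactation_length]")
  }
  out <- rep("mid", length(n))
  out[n == 0] <- "dry"
  out[n >= 1 & n <= 3] <- "early"
  out[n > pmax(lactation_length - 3, 3)] <- "late"
  out[n == 0] <- "dry"
  factor(out, levels = c("early", "mid", "late", "dry"))
}

#' Lactation-stage partitioning fractions
#'
#' Fraction of the metabolizable-energy intake available for performance
#' (after maintenance, activity and gestation) that is directed to milk
#' production, by stage of lactation and diet type.  For diets containing
#' concentrates the fractions are 1.00, 0.88 and 0.80 of the available MEI
#' in early, mid and late lactation; for forage-only diets 1.00, 0.85 and
#' 0.74.  The remainder is available for body-weight gain.
#'
#' @param contains_concentrate Does the diet include concentrates?
#' @return Named numeric vector with elements `early`, `mid`, `late`.
#' @examples
#' stage_fractions(FALSE)
#' @export
stage_fractions <- function(contains_concentrate = FALSE) {
  if (isTRUE(contains_concentrate)) {
    c(early = 1.00, mid = 0.88, late = 0.80)
  } else {
    c(early = 1.00, mid = 0.85, late = 0.74)
  }
}
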