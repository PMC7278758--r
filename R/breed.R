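#' Breed parameters
#'
#' Bundles the genetic and biological constants that describe a breed (or a
#' breed-by-parity class) of dairy cattle: the body-weight frame (birth
#' weight, minimum mature weight and genetic maximum attainable weight), the
#' Gompertz growth coefficient, the lactation-curve parameters (peak milk
#' yield and the month in which it occurs), milk composition, and the partial
#' efficiency of metabolizable-energy use for lactation (`kl`).
#'
#' `kl` defaults to 0.6 for *Bos taurus x Bos indicus* crossbreds and 0.53
#' for *Bos indicus* breeds; pass a value explicitly to override.
#'
#' @param name Breed label.
#' @param species_class `"crossbred"` (*B. taurus x B. indicus*) or
#'   `"indicus"`.
#' @param sex `"female"` or `"male"`.
#' @param birth_weight Body weight at birth (kg).
#' @param max_attainable_weight Genetic maximum body weight (kg).  Mature
#'   weight under (sub-)tropical feeding is taken as 90% of this value.
#' @param min_mature_weight Lower bound of the mature body-weight envelope
#'   (kg), i.e. the asymptote of the minimum-weight trajectory used by the
#'   condition index.
#' @param gompertz_mu0 Gompertz coefficient: initial relative growth rate
#'   (1/day).  Default 0.015 for cattle.
#' @param max_daily_gain Cap on the potential daily body-weight gain
#'   (kg/day).  Default 1.2.
#' @param peak_milk_yield Peak milk yield during lactation (kg/animal/day).
#' @param peak_month Month of lactation in which the peak occurs.
#' @param lactation_length Length of lactation (months).
#' @param milk_fat Milk fat concentration (g/kg milk).
#' @param milk_protein Milk protein concentration (g/kg milk).
#' @param kl Efficiency of ME use for lactation; defaults by
#'   `species_class`.
#'
#' @return An object of class `breed_parameters` (a validated named list).
#' @examples
#' b <- breed_parameters(
#'   name = "crossbred dairy cow", species_class = "crossbred",
#'   sex = "female", birth_weight = 30, max_attainable_weight = 550,
#'   min_mature_weight = 300, peak_milk_yield = 20, peak_month = 2,
#'   lactation_length = 10, milk_fat = 46.3, milk_protein = 29
#' )
#' b$kl
#' @export
breed_parameters <- function(name,
                             species_class = c("crossbred", "indicus"),
                             sex = c("female", "male"),
                             birth_weight,
                             max_attainable_weight,
                             min_mature_weight,
                             gompertz_mu0 = 0.015,
                             max_daily_gain = 1.2,
                             peak_milk_yield,
                             peak_month,
                             lactation_length,
                             milk_fat,
                             milk_protein = NA_real_,
                             kl = NULL) {
  species_class <- check_choice(species_class[[1]], "species_class",
                                c("crossbred", "indicus"))
  sex <- check_choice(sex[[1]], "sex", c("female", "male"))
  if (is.null(kl)) kl <- if (species_class == "crossbred") 0.6 else 0.53

  x <- list(
    name = as.character(name)[[1]],
    species_class = species_class,
    sex = sex,
    birth_weight = check_number(birth_weight, "birth_weight", min = 0,
                                strict_min = TRUE),
    max_attainable_weight = check_number(max_attainable_weight,
                                         "max_attainable_weight", min = 0,
                                         strict_min = TRUE),
    min_mature_weight = check_number(min_mature_weight, "min_mature_weight",
                                     min = 0, strict_min = TRUE),
    gompertz_mu0 = check_number(gompertz_mu0, "gompertz_mu0", min = 0,
                                max = 0.1, strict_min = TRUE),
    max_daily_gain = check_number(max_daily_gain, "max_daily_gain", min = 0,
                                  strict_min = TRUE),
    peak_milk_yield = check_number(peak_milk_yield, "peak_milk_yield",
                                   min = 0, strict_min = TRUE),
    peak_month = check_number(peak_month, "peak_month", min = 1),
    lactation_length = check_number(lactation_length, "lactation_length",
                                    min = 1),
    milk_fat = check_number(milk_fat, "milk_fat", min = 0, strict_min = TRUE),
    milk_protein = if (is.na(milk_protein)) NA_real_ else
      check_number(milk_protein, "milk_protein", min = 0),
    kl = check_number(kl, "kl", min = 0, max = 1, strict_min = TRUE)
  )

  if (!(x$birth_weight < x$min_mature_weight &&
        x$min_mature_weight < x$max_attainable_weight)) {
    stop_invalid(sprintf(
      "weights must satisfy birth (%g) < min mature (%g) < max attainable (%g)",
      x$birth_weight, x$min_mature_weight, x$max_attainable_weight))
  }
  if (x$peak_month > x$lactation_length) {
    stop_invalid(sprintf("peak_month (%g) must not exceed lactation_length (%g)",
                         x$peak_month, x$lactation_length))
  }
  structure(x, class = "breed_parameters")
}

#' @export
print.breed_parameters <- function(x, ...) {
  cat("<breed_parameters> ", x$name, "\n", sep = "")
  cat(sprintf("  %s %s; BW birth %g kg, mature envelope [%g, %g x 0.9] kg\n",
              x$sex, x$species_class, x$birth_weight, x$min_mature_weight,
              x$max_attainable_weight))
  cat(sprintf("  peak milk %g kg/d at month %g of %g; fat %g g/kg; kl %g\n",
              x$peak_milk_yield, x$peak_month, x$lactation_length,
              x$milk_fat, x$kl))
  invisible(x)
}

#' Animal state
#'
#' One animal's time-varying state: age, body weight and reproductive
#' status.  `lactation_month` counts months since calving (first month of
#' lactation is 1); zero means the animal is dry.  `gestation_day` counts
#' days since conception; zero means not pregnant.
#'
#' @param age Age in years.
#' @param body_weight Body weight (kg).
#' @param lactation_month Months since calving (0 = dry).
#' @param gestation_day Days since conception (0 = not pregnant).
#' @param parity Number of previous calvings.
#' @return An object of class `animal_state`.
#' @examples
#' animal_state(age = 5.2, body_weight = 415, lactation_month = 1)
#' @export
animal_state <- function(age, body_weight, lactation_month = 0,
                         gestation_day = 0, parity = 0) {
  x <- list(
    age = check_number(age, "age", min = 0),
    body_weight = check_number(body_weight, "body_weight", min = 0,
                               strict_min = TRUE),
    lactation_month = check_number(lactation_month, "lactation_month", min = 0),
    gestation_day = check_number(gestation_day, "gestation_day", min = 0,
                                 max = 283),
    parity = check_number(parity, "parity", min = 0)
  )
  structure(x, class = "animal_state")
}

#' @export
print.animal_state <- function(x, ...) {
  cat(sprintf("<animal_state> age %.2f y, BW %g kg, lactation month %g, gestation day %g, parity %g\n",
              x$age, x$body_weight, x$lactation_month, x$gestation_day,
              x$parity))
  invisible(x)
}

#' Ration
#'
#' A diet's nutrient concentrations plus the daily feed allowance.
#'
#' @param dm Dry-matter concentration of the feed as fed (g/kg).
#' @param me Metabolizable-energy concentration (MJ/kg DM).
#' @param ndf Neutral detergent fiber concentration (kg/kg DM), in (0, 1).
#' @param cp Crude-protein concentration (g/kg DM).
#' @param contains_concentrate Does the diet include concentrate feeds?
#'   Selects the lactation-stage partitioning fractions.
#' @param offered_dm Feed dry matter offered (kg/animal/day); `Inf` means
#'   ad-libitum feeding.
#' @return An object of class `ration`.
#' @examples
#' ration(dm = 890, me = 9.4, ndf = 0.55, cp = 93.1)
#' @export
ration <- function(dm, me, ndf, cp, contains_concentrate = FALSE,
                   offered_dm = Inf) {
  x <- list(
    dm = check_number(dm, "dm", min = 0, strict_min = TRUE, max = 1000),
    me = check_number(me, "me", min = 0, strict_min = TRUE),
    ndf = check_number(ndf, "ndf", min = 0, max = 1, strict_min = TRUE,
                       strict_max = TRUE),
    cp = check_number(cp, "cp", min = 0),
    contains_concentrate = check_flag(contains_concentrate,
                                      "contains_concentrate"),
    offered_dm = check_number(offered_dm, "offered_dm", min = 0,
                              strict_min = TRUE, allow_inf = TRUE)
  )
  structure(x, class = "ration")
}

#' @export
print.ration <- function(x, ...) {
  cat(sprintf("<ration> ME %g MJ/kg DM, NDF %g kg/kg DM, CP %g g/kg DM, offered %s kg DM/d%s\n",
              x$me, x$ndf, x$cp,
              if (is.finite(x$offered_dm)) format(x$offered_dm) else "ad-lib",
              if (x$contains_concentrate) ", with concentrate" else ""))
  invisible(x)
}
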