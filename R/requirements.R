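## Factorial metabolizable-energy (ME, MJ/d) and utilizable-crude-protein
## (uCP, g/d) requirements.  Each metabolic function is costed separately
## and summed; the age-dependent net costs of body-weight change are
## piecewise-linear interpolations of the packaged lookup tables.

## efficiency of ME utilization for protein and fat deposition
KPF <- 0.4
## efficiency with which net energy mobilized from body reserves is re-used
K_MOBILIZATION <- 0.84

#' Age-dependent net costs of body-weight change
#'
#' Net energy (MJ/kg body-weight change) and net protein (g/kg body-weight
#' gain) for female and male zebu (*B. indicus*) and crossbred
#' (*B. indicus x B. taurus*) cattle at ages 0, 0.1, 1.5, 3.0, 4.5, 5.5
#' and 20 years, reflecting the retarded body-weight development relative
#' to age common under (sub-)tropical husbandry.  Values between the age
#' knots are interpolated linearly with constant extrapolation beyond the
#' last knot; [me_per_kg_gain()] converts net energy to an ME cost by
#' dividing by the deposition efficiency \eqn{k_{pf}} = 0.4.
#'
#' @return A tibble with columns `sex`, `species_class`, `age`,
#'   `net_energy` (MJ/kg) and `net_protein` (g/kg).
#' @examples
#' gain_cost_table()
#' @export
gain_cost_table <- function() {
  if (is.null(the$gain_costs)) {
    e <- read.csv(system.file("extdata", "gain_energy_costs.csv",
                              package = "dairysim", mustWork = TRUE))
    p <- read.csv(system.file("extdata", "gain_protein_costs.csv",
                              package = "dairysim", mustWork = TRUE))
    the$gain_costs <- as_tibble(merge(e, p,
                                      by = c("sex", "species_class", "age")))
  }
  the$gain_costs
}

lookup_gain_cost <- function(age, sex, species_class, column,
                             table = gain_cost_table()) {
  rows <- table[table$sex == sex & table$species_class == species_class, ]
  if (nrow(rows) == 0) {
    stop_invalid(sprintf("no gain-cost entries for sex = %s, species_class = %s",
                         sex, species_class))
  }
  rows <- rows[order(rows$age), ]
  approx(rows$age, rows[[column]], xout = age, rule = 2)$y
}

#' ME requirement for maintenance
#'
#' \eqn{ME_m = b \cdot BW^{0.75}} with `b` = 0.53 MJ/kg^0.75 for calves and
#' 0.631 MJ/kg^0.75 for all other animals, the daily ME requirement per kg
#' metabolic body weight of cattle in the (Sub-)Tropics.
#'
#' @param bw Body weight (kg); vectorized.
#' @param is_calf Use the calf coefficient?
#' @return ME requirement (MJ/day).
#' @examples
#' me_maintenance(415)
#' @export
me_maintenance <- function(bw, is_calf = FALSE) {
  if (any(bw <= 0)) stop_domain("body weight must be positive")
  b <- if (isTRUE(is_calf)) 0.53 else 0.631
  b * bw^0.75
}

#' ME requirement per kg of milk
#'
#' \eqn{(0.041 \cdot milk\,fat + 1.51) / k_l}, with milk fat in g/kg milk
#' and \eqn{k_l} the efficiency of ME use for lactation (0.6 for
#' crossbreds, 0.53 for *B. indicus*).
#'
#' @param milk_fat Milk fat concentration (g/kg milk).
#' @param kl Efficiency of ME use for lactation, in (0, 1].
#' @return ME cost of milk (MJ/kg milk).
#' @examples
#' me_per_kg_milk(46.3, 0.6)
#' @export
me_per_kg_milk <- function(milk_fat, kl) {
  if (any(kl <= 0)) stop_domain("kl must be positive")
  (0.041 * milk_fat + 1.51) / kl
}

#' ME requirement for lactation
#'
#' The ME cost per kg of milk ([me_per_kg_milk()]) times the potential
#' milk yield of the month.
#'
#' @param potential_yield Potential milk yield (kg/animal/day).
#' @param milk_fat Milk fat concentration (g/kg milk).
#' @param kl Efficiency of ME use for lactation.
#' @return ME requirement (MJ/day).
#' @export
me_lactation <- function(potential_yield, milk_fat, kl) {
  me_per_kg_milk(milk_fat, kl) * potential_yield
}

#' ME requirement for activity
#'
#' Net energy of locomotion (2.6 J/kg/m horizontally, 28 J/kg/m
#' vertically), converted to MJ and divided by the efficiency of ME use
#' for activity (0.7).  Zero for stall-fed animals.
#'
#' @param bw Body weight (kg).
#' @param horizontal_distance,vertical_distance Distances covered daily (m).
#' @return ME requirement (MJ/day).
#' @examples
#' me_activity(400, 1000, 0)
#' @export
me_activity <- function(bw, horizontal_distance = 0, vertical_distance = 0) {
  if (any(horizontal_distance < 0) || any(vertical_distance < 0)) {
    stop_domain("activity distances must be non-negative")
  }
  (2.6 * bw * horizontal_distance / 1e6 +
     28 * bw * vertical_distance / 1e6) / 0.7
}

#' ME requirement for gestation
#'
#' \eqn{0.044 \, e^{0.0165 \cdot d} / k_g} with `d` the days since
#' conception and \eqn{k_g} = 0.2 the efficiency of ME use for gestation.
#' The cost is charged only during the last eight weeks (56 days) of
#' gestation; earlier in pregnancy, and for open animals
#' (`gestation_day = 0`), it is zero.
#'
#' @param gestation_day Days since conception (0 = not pregnant).
#' @param term Gestation length (days); default 280.
#' @return ME requirement (MJ/day).
#' @examples
#' me_gestation(280)
#' me_gestation(100)
#' @export
me_gestation <- function(gestation_day, term = DEFAULT_GESTATION_TERM) {
  if (any(gestation_day < 0)) stop_domain("gestation_day must be non-negative")
  out <- 0.044 * exp(0.0165 * gestation_day) / 0.2
  out[gestation_day == 0 | gestation_day < term - 56] <- 0
  out
}

#' ME requirement per kg of body-weight gain
#'
#' The age-dependent net energy content of gain ([gain_cost_table()])
#' interpolated at the animal's age and divided by the efficiency of ME
#' use for protein and fat deposition (\eqn{k_{pf}} = 0.4).
#'
#' @param age Age (years); vectorized.
#' @param sex `"female"` or `"male"`.
#' @param species_class `"crossbred"` or `"indicus"`.
#' @param table Lookup table, by default [gain_cost_table()].
#' @return ME cost of gain (MJ/kg).
#' @examples
#' me_per_kg_gain(3, "female", "crossbred")
#' @export
me_per_kg_gain <- function(age, sex, species_class,
                           table = gain_cost_table()) {
  if (any(age < 0)) stop_domain("age must be non-negative")
  lookup_gain_cost(age, sex, species_class, "net_energy", table) / KPF
}

#' uCP requirement for body-weight gain
#'
#' The age-dependent net protein content of gain ([gain_cost_table()])
#' times the daily gain times 2.1, the factor converting net protein
#' accretion to utilizable crude protein at the duodenum.
#'
#' @inheritParams me_per_kg_gain
#' @param gain Daily body-weight gain (kg/day), non-negative.
#' @return uCP requirement (g/day).
#' @examples
#' ucp_gain(3, "female", "crossbred", gain = 0.5)
#' @export
ucp_gain <- function(age, sex, species_class, gain,
                     table = gain_cost_table()) {
  if (any(gain < 0)) stop_domain("gain must be non-negative; losses carry no deposition requirement")
  lookup_gain_cost(age, sex, species_class, "net_protein", table) * gain * 2.1
}

#' uCP requirements for maintenance, lactation and gestation
#'
#' Utilizable crude protein (uCP) is the sum of undegraded feed protein
#' and microbial protein at the duodenum.  These three components use
#' simple coefficient forms with configurable defaults:
#' maintenance scales with metabolic body weight
#' (`coef` g/kg^0.75/day, default 3.9), lactation with milk yield
#' (`coef` g/kg milk, default 85), and gestation is a constant daily
#' allowance (default 135 g/day) charged over the last eight weeks of
#' gestation only.  uCP balances are reported in the simulation trace but
#' do not feed back on intake or performance.
#'
#' @param bw Body weight (kg).
#' @param coef Coefficient; see Details above for units and defaults.
#' @return uCP requirement (g/day).
#' @export
ucp_maintenance <- function(bw, coef = 3.9) {
  if (any(bw <= 0)) stop_domain("body weight must be positive")
  coef * bw^0.75
}

#' @rdname ucp_maintenance
#' @param milk_yield Milk yield (kg/day).
#' @export
ucp_lactation <- function(milk_yield, coef = 85) {
  coef * pmax(milk_yield, 0)
}

#' @rdname ucp_maintenance
#' @param gestation_day Days since conception (0 = not pregnant).
#' @param term Gestation length (days).
#' @export
ucp_gestation <- function(gestation_day, coef = 135,
                          term = DEFAULT_GESTATION_TERM) {
  out <- rep(coef, length(gestation_day))
  out[gestation_day == 0 | gestation_day < term - 56] <- 0
  out
}

#' Total factorial ME and uCP requirements
#'
#' Sums the per-function metabolizable-energy requirements
#' (maintenance + lactation + activity + gestation + gain) and utilizable
#' crude protein requirements (maintenance + lactation + gestation +
#' gain) for one animal and one monthly step.  The gain and lactation
#' terms are costed at the animal's *potential* performance: the potential
#' Gompertz growth rate and the condition-modified potential milk yield.
#' A negative potential gain contributes no deposition requirement.
#'
#' @param state An [animal_state()].
#' @param breed A [breed_parameters()].
#' @param scenario_settings A [scenario()] (only the activity distances and
#'   the calf age threshold are used), or `NULL` for a stall-fed adult.
#' @param potential_gain Potential daily gain (kg/day).
#' @param potential_yield Potential milk yield for the month
#'   (kg/animal/day).
#' @param gestation_term Gestation length (days).
#' @return One-row tibble with columns `me_maintenance`, `me_lactation`,
#'   `me_activity`, `me_gestation`, `me_gain`, `me_total`,
#'   `ucp_maintenance`, `ucp_lactation`, `ucp_gestation`, `ucp_gain`,
#'   `ucp_total` (ME in MJ/day, uCP in g/day).
#' @examples
#' st <- animal_state(age = 5.2, body_weight = 415, lactation_month = 1)
#' b <- breed_parameters("x", "crossbred", "female", 30, 500, 280,
#'                       peak_milk_yield = 20, peak_month = 2,
#'                       lactation_length = 10, milk_fat = 46.3)
#' total_requirements(st, b, NULL, potential_gain = 0.2,
#'                    potential_yield = 13)
#' @export
total_requirements <- function(state, breed, scenario_settings = NULL,
                               potential_gain = 0, potential_yield = 0,
                               gestation_term = DEFAULT_GESTATION_TERM) {
  horiz <- scenario_settings$horizontal_distance %||% 0
  vert <- scenario_settings$vertical_distance %||% 0
  is_calf <- state$age < 1

  gain_dep <- max(potential_gain, 0)
  me_m <- me_maintenance(state$body_weight, is_calf)
  me_l <- me_lactation(potential_yield, breed$milk_fat, breed$kl)
  me_a <- me_activity(state$body_weight, horiz, vert)
  me_g <- me_gestation(state$gestation_day, term = gestation_term)
  me_pf <- me_per_kg_gain(state$age, breed$sex, breed$species_class) * gain_dep

  ucp_m <- ucp_maintenance(state$body_weight)
  ucp_l <- ucp_lactation(potential_yield)
  ucp_g <- ucp_gestation(state$gestation_day, term = gestation_term)
  ucp_pf <- ucp_gain(state$age, breed$sex, breed$species_class, gain_dep)

  tibble(
    me_maintenance = me_m, me_lactation = me_l, me_activity = me_a,
    me_gestation = me_g, me_gain = me_pf,
    me_total = me_m + me_l + me_a + me_g + me_pf,
    ucp_maintenance = ucp_m, ucp_lactation = ucp_l, ucp_gestation = ucp_g,
    ucp_gain = ucp_pf,
    ucp_total = ucp_m + ucp_l + ucp_g + ucp_pf
  )
}
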