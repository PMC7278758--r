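#' Partition one step's metabolizable-energy intake
#'
#' Allocates the metabolizable-energy intake (MEI) of one monthly step
#' among the animal's metabolic functions in priority order maintenance ->
#' activity -> gestation -> milk -> gain, applying the body-reserve
#' mobilization rules of early lactation:
#'
#' * The MEI left after maintenance, activity and gestation is the *MEI
#'   available for performance*.  A stage- and diet-specific fraction of
#'   it ([stage_fractions()]) goes to milk, capped at the energy cost of
#'   the month's potential milk yield; the remainder (including any
#'   spill-over beyond that cap) goes to body-weight gain at the
#'   age-dependent ME cost per kg gain.
#' * If MEI falls short of the maintenance(+activity+gestation)
#'   obligations, body weight is mobilized for survival, at most 0.23% of
#'   body weight per day.
#' * In early lactation (months 1--3) cows may additionally mobilize body
#'   weight -- within the same daily 0.23% cap -- to raise milk output up
#'   to 60% of the potential yield when the MEI-funded milk falls short of
#'   that level.  Milk already funded by MEI is never cut back.
#' * Beyond month 3 no reserves are mobilized for milk, and milk ceases
#'   entirely if MEI remains below maintenance.
#'
#' Mobilized tissue is valued at the age-dependent net energy per kg of
#' body-weight change, re-used with an efficiency of 0.84: credited
#' directly against a maintenance-side energy deficit, or converted to
#' milk through the net (fat-dependent) energy cost per kg of milk, so
#' that one kg of tissue supports `NE x 0.84 / (0.041 x fat + 1.51)` kg
#' of milk.  Energy closes exactly: `mei + mobilized_me` equals the sum
#' of the five `me_to_*` allocations (mobilized energy expressed in
#' ME-equivalents of the function it funds).
#'
#' @param mei Metabolizable-energy intake (MJ/day), non-negative.
#' @param req A one-row requirement tibble from [total_requirements()]
#'   (only the maintenance, activity and gestation components are read;
#'   milk and gain are allocated from the surplus).
#' @param state An [animal_state()].
#' @param breed A [breed_parameters()].
#' @param feed A [ration()]; its `contains_concentrate` flag selects the
#'   stage fractions.
#' @param potential_milk Condition-modified potential milk yield of the
#'   month (kg/animal/day).
#' @return One-row tibble with columns `mei`, `me_to_maintenance`,
#'   `me_to_activity`, `me_to_gestation`, `me_to_milk`, `me_to_gain` (all
#'   MJ/d), `mobilized_bw` (kg/d, >= 0), `mobilized_me` (MJ/d),
#'   `actual_milk` (kg/d), `actual_gain` (kg/d, may be negative) and
#'   `lactation_stage`.
#' @examples
#' b <- breed_parameters("x", "crossbred", "female", 30, 500, 280,
#'                       peak_milk_yield = 20, peak_month = 2,
#'                       lactation_length = 10, milk_fat = 46.3)
#' st <- animal_state(age = 5.2, body_weight = 415, lactation_month = 1)
#' r <- ration(dm = 890, me = 9.4, ndf = 0.55, cp = 93.1)
#' req <- total_requirements(st, b, NULL, 0.2, 13)
#' partition_step(95, req, st, b, r, potential_milk = 13)
#' @export
partition_step <- function(mei, req, state, breed, feed, potential_milk) {
  if (mei < 0) stop_domain("MEI must be non-negative")
  if (potential_milk < 0) stop_domain("potential milk must be non-negative")

  stage <- as.character(lactation_stage(state$lactation_month,
                                        breed$lactation_length))
  fr <- stage_fractions(feed$contains_concentrate)

  milk_cost <- me_per_kg_milk(breed$milk_fat, breed$kl)   # MJ ME/kg milk
  gain_cost <- me_per_kg_gain(state$age, breed$sex, breed$species_class)
  tissue_ne <- gain_cost * KPF              # net energy of 1 kg body tissue
  ## Mobilized tissue yields net energy, re-used at 0.84.  Against the
  ## (ME-scale) maintenance deficit it is credited as NE x 0.84; routed to
  ## milk it covers the *net* milk cost, i.e. 1 kg tissue supports
  ## NE x 0.84 / (0.041 x fat + 1.51) kg of milk, which in ME-equivalents
  ## is worth NE x 0.84 / kl per kg.
  mob_value_survival <- tissue_ne * K_MOBILIZATION
  milk_per_kg_mob <- tissue_ne * K_MOBILIZATION /
    (0.041 * breed$milk_fat + 1.51)
  mob_cap <- 0.0023 * state$body_weight                   # kg/day

  obligations <- req$me_maintenance + req$me_activity + req$me_gestation

  ## survival mobilization: cover an energy deficit, any stage, capped
  mob_survival <- 0
  if (mei < obligations) {
    mob_survival <- min((obligations - mei) / mob_value_survival, mob_cap)
  }
  surplus <- max(mei + mob_survival * mob_value_survival - obligations, 0)

  ## milk funded by the intake surplus
  lactating <- stage != "dry" && potential_milk > 0
  milk_me_from_mei <- if (lactating) {
    min(fr[[stage]] * surplus, potential_milk * milk_cost)
  } else 0
  milk_from_mei <- milk_me_from_mei / milk_cost

  ## early-lactation top-up from body reserves, sharing the daily cap
  mob_milk <- 0
  if (lactating && stage == "early") {
    target <- 0.6 * potential_milk
    shortfall_kg <- max(target - milk_from_mei, 0)
    mob_milk <- min(shortfall_kg / milk_per_kg_mob,
                    max(mob_cap - mob_survival, 0))
  }
  mobilized_bw <- mob_survival + mob_milk
  mobilized_me <- mob_survival * mob_value_survival +
    mob_milk * milk_per_kg_mob * milk_cost

  actual_milk <- milk_from_mei + mob_milk * milk_per_kg_mob
  me_to_milk <- actual_milk * milk_cost
  me_to_gain <- surplus - milk_me_from_mei
  actual_gain <- me_to_gain / gain_cost - mobilized_bw

  ## sequential allocation of the pool to the obligations, for exact closure
  pool <- mei + mobilized_me
  me_to_maint <- min(pool, req$me_maintenance)
  pool <- pool - me_to_maint
  me_to_act <- min(pool, req$me_activity)
  pool <- pool - me_to_act
  me_to_gest <- min(pool, req$me_gestation)

  tibble(
    mei = mei,
    me_to_maintenance = me_to_maint,
    me_to_activity = me_to_act,
    me_to_gestation = me_to_gest,
    me_to_milk = me_to_milk,
    me_to_gain = me_to_gain,
    mobilized_bw = mobilized_bw,
    mobilized_me = mobilized_me,
    actual_milk = actual_milk,
    actual_gain = actual_gain,
    lactation_stage = stage
  )
}
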