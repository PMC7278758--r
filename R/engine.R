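#' Run a monthly time-step simulation
#'
#' Simulates one animal for `n_steps` monthly steps.  Each step executes,
#' in order: (1) potential daily gain from the Gompertz growth curve;
#' (2) potential milk yield from the lactation curve, modified by the
#' body-weight condition index raised to the scenario's
#' `milk_condition_exponent` (and an age factor, fixed at 1);
#' (3) factorial potential ME and uCP requirements; (4) voluntary
#' dry-matter intake and ME intake; (5) ME partitioning with the
#' early-lactation mobilization rules; (6) state update: body weight
#' changes by `actual_gain * days_per_step`, age advances by
#' `days_per_step / 365.25` years, the lactation month advances by 1 while
#' the animal is lactating (drying off after `lactation_length` months),
#' and the gestation day advances by `days_per_step` while pregnant.
#' The simulation is fully deterministic.
#'
#' @param sc A [scenario()].
#' @return A `sim_trace`: a tibble with one row per step holding the
#'   start-of-step state (`age`, `body_weight`, `lactation_month`,
#'   `condition_index`), the potential performance (`potential_gain`,
#'   `potential_milk`), the intake block (`ndf_capacity` ... `mei`), the
#'   requirement block (`me_*`, `ucp_*`), the partition block
#'   (`me_to_*`, `mobilized_*`, `actual_milk`, `actual_gain`,
#'   `lactation_stage`) and the running aggregates `cumulative_milk` (kg)
#'   and `mean_dmi_to_date` (kg/d).  The scenario is attached as the
#'   `"scenario"` attribute; see [glance.sim_trace()] for the run summary.
#' @examples
#' trace <- run_simulation(builtin_fixture("maize_lablab"))
#' dplyr::select(trace, step, body_weight, scaled_dmi, actual_milk)
#' glance(trace)
#' @export
run_simulation <- function(sc) {
  if (!inherits(sc, "scenario")) stop_schema("`sc` must be a scenario object")
  breed <- sc$breed
  feed <- sc$ration
  env <- growth_envelope(breed)
  days <- sc$days_per_step

  age <- sc$initial_state$age
  bw <- sc$initial_state$body_weight
  lac <- sc$initial_state$lactation_month
  gest <- sc$initial_state$gestation_day
  parity <- sc$initial_state$parity

  rows <- vector("list", sc$n_steps)
  for (step in seq_len(sc$n_steps)) {
    state <- animal_state(age = age, body_weight = bw, lactation_month = lac,
                          gestation_day = min(gest, 283), parity = parity)
    idx <- condition_index(bw, age, env)
    pot_gain <- potential_growth_rate(bw, breed)
    pot_milk <- potential_milk_yield(lac, breed) *
      idx^sc$milk_condition_exponent * milk_age_factor(state)

    req <- total_requirements(state, breed, sc,
                              potential_gain = pot_gain,
                              potential_yield = pot_milk)
    intake <- voluntary_dmi(bw, req$me_total, feed, idx)
    part <- partition_step(intake$mei, req, state, breed, feed, pot_milk)

    rows[[step]] <- dplyr::bind_cols(
      tibble(step = step, days_in_step = days, age = age, body_weight = bw,
             lactation_month = lac, gestation_day = state$gestation_day,
             condition_index = idx, potential_gain = pot_gain,
             potential_milk = pot_milk),
      intake, req, part[setdiff(names(part), "mei")]
    )

    bw <- bw + part$actual_gain * days
    if (bw <= 0) {
      abort(sprintf("body weight fell to %.1f kg at step %d", bw, step),
            class = "dairysim_simulation_error")
    }
    age <- age + days / 365.25
    if (lac >= 1) lac <- if (lac >= breed$lactation_length) 0 else lac + 1
    if (gest > 0) gest <- gest + days
  }

  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(
    out,
    cumulative_milk = cumsum(.data$actual_milk * .data$days_in_step),
    mean_dmi_to_date = cumsum(.data$scaled_dmi) / .data$step
  )
  attr(out, "scenario") <- sc
  attr(out, "final_body_weight") <-
    out$body_weight[nrow(out)] + out$actual_gain[nrow(out)] * days
  class(out) <- c("sim_trace", class(out))
  out
}

## Hook for an age-dependent multiplier on potential milk yield.  The
## published multipliers for age and parity are not reproducible from the
## available sources, so the factor is fixed at 1; override by masking
## this function in a fork if breed-specific curves become available.
milk_age_factor <- function(state) 1

#' Summarize a simulation trace
#'
#' @param x A `sim_trace` from [run_simulation()].
#' @param ... Unused.
#' @return One-row tibble: `n_steps`, `days_per_step`, `initial_bw` and
#'   `final_bw` (kg), `mean_dmi` and `final_dmi` (kg/d), `mean_milk` and
#'   `final_milk` (kg/d), `total_milk` (kg), `total_bw_change` (kg).
#' @exportS3Method generics::glance
glance.sim_trace <- function(x, ...) {
  n <- nrow(x)
  tibble(
    n_steps = n,
    days_per_step = x$days_in_step[1],
    initial_bw = x$body_weight[1],
    final_bw = attr(x, "final_body_weight"),
    mean_dmi = mean(x$scaled_dmi),
    final_dmi = x$scaled_dmi[n],
    mean_milk = mean(x$actual_milk),
    final_milk = x$actual_milk[n],
    total_milk = x$cumulative_milk[n],
    total_bw_change = attr(x, "final_body_weight") - x$body_weight[1]
  )
}

#' Tidy a simulation trace
#'
#' Returns the per-step records in long form: one row per step and
#' reported quantity, convenient for faceted plotting.
#'
#' @param x A `sim_trace`.
#' @param ... Unused.
#' @return A tibble with columns `step`, `quantity`, `value`.
#' @exportS3Method generics::tidy
tidy.sim_trace <- function(x, ...) {
  keep <- c("body_weight", "condition_index", "scaled_dmi", "mei",
            "potential_milk", "actual_milk", "actual_gain", "mobilized_bw",
            "me_total", "ucp_total")
  tidyr::pivot_longer(
    dplyr::select(as_tibble(x), "step", dplyr::all_of(keep)),
    -"step", names_to = "quantity", values_to = "value"
  )
}

#' Write or read a simulation trace as CSV
#'
#' `write_trace()` stores one data row per step plus a final summary row
#' (`record_type = "summary"`) carrying the run's mean voluntary DMI (in
#' `scaled_dmi`), final body weight (in `body_weight`) and mean daily milk
#' yield (in `actual_milk`).  `read_trace()` reads the per-step records
#' back; numeric fields round-trip to full precision.
#'
#' @param trace A `sim_trace` from [run_simulation()].
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` a
#'   tibble of per-step records.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "sim_trace") || nrow(trace) == 0) {
    stop_schema("`trace` must be a non-empty simulation trace")
  }
  g <- glance.sim_trace(trace)
  df <- as.data.frame(trace)
  df <- cbind(record_type = "step", df)
  summary_row <- df[1, ]
  summary_row[1, ] <- NA
  summary_row$record_type <- "summary"
  summary_row$scaled_dmi <- g$mean_dmi
  summary_row$body_weight <- g$final_bw
  summary_row$actual_milk <- g$mean_milk
  summary_row$cumulative_milk <- g$total_milk
  out <- rbind(df, summary_row)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("trace file not found: ", path), class = "dairysim_io_error")
  }
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  dplyr::select(dplyr::filter(df, .data$record_type == "step"),
                -"record_type")
}
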