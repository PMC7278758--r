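#' Model-adequacy statistics
#'
#' Paired observed/predicted comparison statistics used to judge the
#' simulator:
#' * `mean_bias_error()`: \eqn{\sum_i (obs_i - pred_i) / q}, where `q` is
#'   the number of pairs.  Negative values indicate over-prediction.
#' * `rmsep()`: root mean squared error of prediction,
#'   \eqn{\sqrt{\sum_i (obs_i - pred_i)^2 / q}}.
#' * `rpe()`: relative prediction error, the RMSEP expressed as a
#'   percentage of the observed mean.
#'
#' @param observed,predicted Equal-length numeric vectors of paired
#'   values (here: treatment means).
#' @return A single number, in the units of the series (`rpe()` in % of
#'   the observed mean).
#' @examples
#' mean_bias_error(c(386, 399), c(385, 383))
#' rmsep(c(386, 399), c(385, 383))
#' rpe(c(386, 399), c(385, 383))
#' @export
mean_bias_error <- function(observed, predicted) {
  check_pairs(observed, predicted)
  mean(observed - predicted)
}

#' @rdname mean_bias_error
#' @export
rmsep <- function(observed, predicted) {
  check_pairs(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

#' @rdname mean_bias_error
#' @export
rpe <- function(observed, predicted) {
  check_pairs(observed, predicted)
  m <- mean(observed)
  if (m == 0) stop_domain("observed mean is zero; RPE undefined")
  100 * rmsep(observed, predicted) / m
}

check_pairs <- function(observed, predicted) {
  if (length(observed) == 0) stop_domain("empty paired series")
  if (length(observed) != length(predicted)) {
    stop_domain("observed and predicted series differ in length")
  }
  if (!all(is.finite(observed)) || !all(is.finite(predicted))) {
    stop_domain("paired series must be finite")
  }
  invisible(TRUE)
}

#' Accuracy class of a relative prediction error
#'
#' Predictions are classified as excellent (RPE < 10%), good (10--20%),
#' fair (21--30%) or poor (> 30%).  The printed interval ends are treated
#' as closed: an RPE of exactly 10 or 20 is good, of exactly 21 or 30
#' fair; values between 20 and 21 fall to fair.
#'
#' @param rpe_value RPE in percent; vectorized.
#' @return Factor with levels `excellent`, `good`, `fair`, `poor`.
#' @examples
#' accuracy_class(c(3, 13.5, 25, 70.5))
#' @export
accuracy_class <- function(rpe_value) {
  if (any(rpe_value < 0)) stop_domain("RPE must be non-negative")
  cls <- ifelse(rpe_value < 10, "excellent",
         ifelse(rpe_value <= 20, "good",
         ifelse(rpe_value <= 30, "fair", "poor")))
  factor(cls, levels = c("excellent", "good", "fair", "poor"))
}

#' Evaluate paired predictions, one report row per parameter
#'
#' Takes a tibble of paired observed/predicted values -- typically one
#' row per parameter and treatment -- and computes the mean bias error,
#' RMSEP, RPE and accuracy class per parameter (or per any grouping
#' columns present beyond `observed`/`predicted`).
#'
#' @param data A data frame with at least the columns named by `observed`
#'   and `predicted`, plus grouping columns (e.g. `parameter`, `model`).
#' @param observed,predicted Column names (strings) of the paired values.
#' @return A tibble with one row per group and columns `n_pairs`, `mbe`,
#'   `rmsep`, `rpe`, `accuracy_class`.
#' @examples
#' observed_performance() |>
#'   dplyr::rename(predicted = reference_model) |>
#'   dplyr::select(parameter, observed, predicted) |>
#'   model_evaluation()
#' @export
model_evaluation <- function(data, observed = "observed",
                             predicted = "predicted") {
  for (col in c(observed, predicted)) {
    if (!col %in% names(data)) {
      stop_schema(paste0("missing column `", col, "`"), field = col)
    }
  }
  group_cols <- setdiff(names(data), c(observed, predicted, "treatment",
                                       "units", "value"))
  out <- dplyr::summarise(
    dplyr::group_by(as_tibble(data), dplyr::across(dplyr::all_of(group_cols))),
    n_pairs = dplyr::n(),
    mbe = mean_bias_error(.data[[observed]], .data[[predicted]]),
    rmsep = rmsep(.data[[observed]], .data[[predicted]]),
    rpe = rpe(.data[[observed]], .data[[predicted]]),
    .groups = "drop"
  )
  dplyr::mutate(out, accuracy_class = accuracy_class(.data$rpe))
}

#' Observed performance of the stall-fed evaluation trial
#'
#' Treatment means for the two bundled evaluation diets (maize--lablab
#' stover and oats--vetch hay, fed ad libitum to multiparous crossbred
#' cows over 140 days postpartum): observed voluntary dry-matter intake
#' (kg/animal/day), final body weight (kg) and daily milk yield
#' (kg/animal/day), together with the corresponding predictions of the
#' unmodified reference herd simulator, which this package treats as
#' printed input data for the evaluation statistics (its internals are
#' not simulated here).
#'
#' @return A tibble with columns `parameter`, `treatment`, `units`,
#'   `observed`, `reference_model`.
#' @examples
#' observed_performance()
#' @export
observed_performance <- function() {
  path <- system.file("extdata", "stallfed_trial_performance.csv",
                      package = "dairysim", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Evaluate simulation traces against observed performance
#'
#' Pairs each trace's headline predictions (mean voluntary DMI, final
#' body weight, mean daily milk yield) with the observed treatment means
#' and computes the adequacy statistics per parameter.
#'
#' @param traces Named list of `sim_trace` objects, one per treatment;
#'   names must match the `treatment` column of `observed`.
#' @param observed A tibble like [observed_performance()]: columns
#'   `parameter` (`dmi`, `final_bw`, `milk_yield`), `treatment` and
#'   `observed`.
#' @return A tibble with one row per parameter: `n_pairs`, `mbe`,
#'   `rmsep`, `rpe`, `accuracy_class`.
#' @examples
#' traces <- list(
#'   maize_lablab = run_simulation(builtin_fixture("maize_lablab")),
#'   oats_vetch = run_simulation(builtin_fixture("oats_vetch"))
#' )
#' evaluate_against_observed(traces)
#' @export
evaluate_against_observed <- function(traces,
                                      observed = observed_performance()) {
  if (is.null(names(traces)) || any(names(traces) == "")) {
    stop_schema("`traces` must be a named list (names = treatments)")
  }
  missing_tr <- setdiff(unique(observed$treatment), names(traces))
  if (length(missing_tr) > 0) {
    abort(paste0("no trace supplied for treatment(s): ",
                 paste(missing_tr, collapse = ", ")),
          class = "dairysim_naming_error")
  }
  predicted <- purrr::map_dfr(names(traces), function(tr) {
    g <- glance.sim_trace(traces[[tr]])
    tibble(
      treatment = tr,
      parameter = c("dmi", "final_bw", "milk_yield"),
      predicted = c(g$mean_dmi, g$final_bw, g$mean_milk)
    )
  })
  joined <- dplyr::inner_join(observed, predicted,
                              by = c("parameter", "treatment"))
  bad <- setdiff(unique(observed$parameter), unique(joined$parameter))
  if (length(bad) > 0) {
    abort(paste0("observed parameter(s) not produced by the traces: ",
                 paste(bad, collapse = ", ")),
          class = "dairysim_naming_error")
  }
  model_evaluation(dplyr::select(joined, "parameter", "observed",
                                 "predicted"))
}
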