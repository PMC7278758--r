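#' Simulation scenario
#'
#' A complete, validated description of one simulation: a breed, an animal's
#' initial state, a ration, and the run settings (number of monthly steps,
#' daily activity distances, and the calendar length of a step).
#'
#' @param breed A [breed_parameters()] object.
#' @param initial_state An [animal_state()] object.
#' @param ration A [ration()] object.
#' @param n_steps Number of monthly time steps to simulate (>= 1).
#' @param horizontal_distance Horizontal distance walked daily (m); 0 for
#'   stall-fed animals.
#' @param vertical_distance Vertical distance climbed daily (m).
#' @param days_per_step Calendar days per step; default 30.4.
#' @param milk_condition_exponent Exponent `g` of the body-weight
#'   condition index in the potential-milk modifier: the month's potential
#'   yield is multiplied by `index^g` before entering the requirement and
#'   partitioning calculations.  `0` disables the modifier, `1` applies
#'   the index linearly.  The default 0.16 is the package's calibrated
#'   value for stall-fed crossbred cows (see the methods vignette).
#' @return An object of class `scenario`.
#' @seealso [read_scenario()], [builtin_fixture()], [run_simulation()]
#' @export
scenario <- function(breed, initial_state, ration, n_steps,
                     horizontal_distance = 0, vertical_distance = 0,
                     days_per_step = DEFAULT_DAYS_PER_STEP,
                     milk_condition_exponent = DEFAULT_MILK_CONDITION_EXPONENT) {
  if (!inherits(breed, "breed_parameters")) {
    stop_schema("`breed` must be a breed_parameters object", field = "breed")
  }
  if (!inherits(initial_state, "animal_state")) {
    stop_schema("`initial_state` must be an animal_state object",
                field = "initial_state")
  }
  if (!inherits(ration, "ration")) {
    stop_schema("`ration` must be a ration object", field = "ration")
  }
  if (initial_state$lactation_month > breed$lactation_length) {
    stop_invalid(sprintf(
      "lactation_month (%g) exceeds the breed's lactation_length (%g)",
      initial_state$lactation_month, breed$lactation_length))
  }
  x <- list(
    breed = breed,
    initial_state = initial_state,
    ration = ration,
    n_steps = as.integer(check_number(n_steps, "n_steps", min = 1)),
    horizontal_distance = check_number(horizontal_distance,
                                       "horizontal_distance", min = 0),
    vertical_distance = check_number(vertical_distance, "vertical_distance",
                                     min = 0),
    days_per_step = check_number(days_per_step, "days_per_step", min = 0,
                                 strict_min = TRUE),
    milk_condition_exponent = check_number(milk_condition_exponent,
                                           "milk_condition_exponent",
                                           min = 0, max = 5)
  )
  structure(x, class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %d monthly steps (%g d each), activity %g m horiz / %g m vert per day\n",
              x$n_steps, x$days_per_step, x$horizontal_distance,
              x$vertical_distance))
  print(x$breed)
  print(x$initial_state)
  print(x$ration)
  invisible(x)
}

scenario_from_list <- function(cfg) {
  need <- function(section) {
    if (is.null(cfg[[section]])) {
      stop_schema(paste0("missing section `", section, "`"), field = section)
    }
    cfg[[section]]
  }
  b <- need("breed"); a <- need("animal"); r <- need("ration")
  s <- need("simulation")
  call_with <- function(fn, args, where) {
    fml <- formals(fn)
    extra <- setdiff(names(args), names(fml))
    if (length(extra) > 0) {
      stop_schema(sprintf("unknown field(s) in `%s`: %s", where,
                          paste(extra, collapse = ", ")))
    }
    required <- names(fml)[vapply(fml, function(d)
      is.symbol(d) && !nzchar(as.character(d)), logical(1))]
    missing_f <- setdiff(required, names(args))
    if (length(missing_f) > 0) {
      stop_schema(sprintf("missing field(s) in `%s`: %s", where,
                          paste(missing_f, collapse = ", ")),
                  field = missing_f[[1]])
    }
    do.call(fn, args)
  }
  scenario(
    breed = call_with(breed_parameters, b, "breed"),
    initial_state = call_with(animal_state, a, "animal"),
    ration = call_with(ration, r, "ration"),
    n_steps = s$n_steps,
    horizontal_distance = s$horizontal_distance %||% 0,
    vertical_distance = s$vertical_distance %||% 0,
    days_per_step = s$days_per_step %||% DEFAULT_DAYS_PER_STEP,
    milk_condition_exponent = s$milk_condition_exponent %||%
      DEFAULT_MILK_CONDITION_EXPONENT
  )
}

scenario_to_list <- function(x) {
  strip <- function(obj) {
    out <- unclass(obj)
    out[!vapply(out, function(v) is.null(v) ||
                  (length(v) == 1 && is.na(v)), logical(1))]
  }
  list(
    breed = strip(x$breed),
    animal = strip(x$initial_state),
    ration = strip(x$ration),
    simulation = list(
      n_steps = x$n_steps,
      horizontal_distance = x$horizontal_distance,
      vertical_distance = x$vertical_distance,
      days_per_step = x$days_per_step,
      milk_condition_exponent = x$milk_condition_exponent
    )
  )
}

#' Read or write a scenario configuration file
#'
#' Scenarios are stored as flat, human-readable YAML files with four
#' sections (`breed`, `animal`, `ration`, `simulation`) whose keys match
#' the arguments of [breed_parameters()], [animal_state()], [ration()] and
#' [scenario()].  All units are as documented for those constructors.
#' `offered_dm: .inf` denotes ad-libitum feeding.  Reading validates every
#' invariant; a scenario round-trips through write/read unchanged.
#'
#' @param path Path to a YAML scenario file.
#' @param x A `scenario` object.
#' @return `read_scenario()` returns a validated `scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @examples
#' sc <- builtin_fixture("maize_lablab")
#' f <- tempfile(fileext = ".yaml")
#' write_scenario(sc, f)
#' identical(read_scenario(f), sc)
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("scenario file not found: ", path),
          class = "dairysim_io_error")
  }
  scenario_from_list(yaml::read_yaml(path))
}

#' @rdname read_scenario
#' @export
write_scenario <- function(x, path) {
  if (!inherits(x, "scenario")) {
    stop_schema("`x` must be a scenario object")
  }
  yaml::write_yaml(scenario_to_list(x), path,
                   precision = 15, indent.mapping.sequence = TRUE)
  invisible(path)
}

#' Bundled evaluation scenarios
#'
#' Two ready-made scenarios describing the stall-fed crossbred dairy cows
#' used to evaluate the simulator: multiparous *B. indicus x B. taurus*
#' cows fed either maize--lablab stover or oats--vetch hay ad libitum,
#' simulated for five monthly steps from calving.  Animal and diet values
#' come from the published feeding trial; the breed's birth weight and
#' body-weight envelope (minimum mature and maximum attainable weight)
#' are not part of the printed trial data and carry the package's
#' calibrated values (see the methods vignette), which users can override
#' by editing a copy of the YAML (see [read_scenario()]).
#'
#' @param name `"maize_lablab"` or `"oats_vetch"`.
#' @return A validated `scenario`.
#' @examples
#' builtin_fixture("maize_lablab")
#' @export
builtin_fixture <- function(name = c("maize_lablab", "oats_vetch")) {
  name <- check_choice(name[[1]], "name", c("maize_lablab", "oats_vetch"))
  path <- system.file("extdata", paste0(name, ".yaml"), package = "dairysim",
                      mustWork = TRUE)
  read_scenario(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
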