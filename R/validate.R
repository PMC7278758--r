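## Internal validation helpers.  All user-facing constructors funnel through
## these so that schema problems (missing fields) and invariant violations
## (out-of-range values) raise distinct, classed conditions.

stop_schema <- function(msg, field = NULL) {
  abort(msg, class = "dairysim_schema_error", field = field)
}

stop_invalid <- function(msg, value = NULL) {
  abort(msg, class = "dairysim_validation_error", value = value)
}

stop_domain <- function(msg) {
  abort(msg, class = "dairysim_domain_error")
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE,
                         allow_inf = FALSE) {
  if (is.null(x)) stop_schema(paste0("missing field `", name, "`"), field = name)
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_schema(paste0("field `", name, "` must be a single number"), field = name)
  }
  if (!allow_inf && !is.finite(x)) {
    stop_schema(paste0("field `", name, "` must be finite"), field = name)
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    stop_invalid(sprintf("field `%s` = %g outside its valid range %s%g, %g%s",
                         name, x,
                         if (strict_min) "(" else "[", min, max,
                         if (strict_max) ")" else "]"),
                 value = x)
  }
  as.numeric(x)
}

check_choice <- function(x, name, choices) {
  if (is.null(x)) stop_schema(paste0("missing field `", name, "`"), field = name)
  if (!is.character(x) || length(x) != 1L || !x %in% choices) {
    stop_invalid(sprintf("field `%s` must be one of: %s",
                         name, paste(choices, collapse = ", ")), value = x)
  }
  x
}

check_flag <- function(x, name) {
  if (is.null(x)) stop_schema(paste0("missing field `", name, "`"), field = name)
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_schema(paste0("field `", name, "` must be TRUE or FALSE"), field = name)
  }
  x
}
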