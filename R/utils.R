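#' @keywords internal
"_PACKAGE"

# Arm labels used throughout; order fixed so per-arm vectors are unambiguous.
ARMS <- c("calcifediol", "calcitriol", "placebo")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_config("%s must lie in [0, 1], got: %s", what, paste(x, collapse = ", "))
  invisible(x)
}

check_arm_vec <- function(x, what) {
  if (is.null(names(x)) || !setequal(names(x), ARMS))
    stop_config("%s must be a named vector over arms %s", what,
                paste(ARMS, collapse = ", "))
  x[ARMS]
}

# Hours from enrollment for calendar day d (day bins are [24 d, 24 d + 24)).
day_to_hours <- function(day) 24 * day

hours_to_day <- function(time_h) floor(time_h / 24)

# Deterministic 31-bit polynomial fingerprint of a character scalar; used
# for run-manifest config hashes so the pipeline needs no external digest.
# (Not cryptographic; collisions are irrelevant for provenance stamps.)
config_fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Construct a laboratory time series
#'
#' A lab series is an ordered data frame of `(time_h, value)` pairs for one
#' analyte, with the analyte name and measurement unit carried as attributes.
#' Times are hours from enrollment and must be strictly increasing;
#' concentration values must be positive.
#'
#' @param analyte Analyte name, e.g. `"scr"`, `"vitd_25"`, `"vitd_125"`,
#'   `"calcium"`, `"phosphate"`, `"uop"`.
#' @param unit Measurement unit, e.g. `"mg/dL"`, `"ng/mL"`, `"pg/mL"`,
#'   `"mL/kg/h"`.
#' @param time_h Numeric vector of observation times in hours from enrollment.
#' @param value Numeric vector of measurements, same length as `time_h`.
#' @return A `data.frame` with columns `time_h` and `value` and attributes
#'   `analyte` and `unit`, of class `lab_series`.
#' @export
#' @examples
#' lab_series("scr", "mg/dL", time_h = c(0, 24, 48), value = c(1.0, 1.2, 1.4))
lab_series <- function(analyte, unit, time_h, value) {
  if (length(time_h) != length(value))
    stop_config("time_h and value must have the same length")
  if (length(time_h) && any(diff(time_h) <= 0))
    stop_config("lab series times must be strictly increasing")
  if (any(!is.finite(value)) || any(value <= 0))
    stop_config("lab series values must be positive and finite (analyte %s)", analyte)
  out <- data.frame(time_h = as.numeric(time_h), value = as.numeric(value))
  attr(out, "analyte") <- analyte
  attr(out, "unit") <- unit
  class(out) <- c("lab_series", "data.frame")
  out
}

# Coerce a plain data.frame with time_h/value columns; used at ingest
# boundaries where attributes may have been dropped by CSV round-trips.
as_series <- function(x) {
  stopifnot(all(c("time_h", "value") %in% names(x)))
  x[order(x$time_h), c("time_h", "value"), drop = FALSE]
}

# Extract one patient's series for one analyte from a long labs table.
labs_for <- function(labs, patient_id, analyte) {
  sel <- labs[labs$patient_id == patient_id & labs$analyte == analyte, , drop = FALSE]
  as_series(sel)
}
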