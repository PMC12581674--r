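#' Event-free days to a horizon
#'
#' ICU- and hospital-free days treat death as a competing risk: patients
#' who die before day `horizon` score exactly 0; survivors score
#' `horizon - stay_days`, floored at 0.
#'
#' @param stay_days Days in ICU (or hospital); vectorized, must be >= 0.
#' @param death_day Day of death or `NA`; recycled against `stay_days`.
#' @param horizon Follow-up horizon in days (default 28).
#' @return Numeric vector of free days in `[0, horizon]`.
#' @export
#' @examples
#' free_days(5, NA)        # 23
#' free_days(5, 10)        # 0: died before day 28
#' free_days(30, NA)       # 0: floor
free_days <- function(stay_days, death_day = NA, horizon = 28) {
  if (any(is.na(stay_days)) || any(stay_days < 0))
    stop_config("stay_days must be nonnegative")
  n <- max(length(stay_days), length(death_day))
  stay_days <- rep_len(stay_days, n)
  death_day <- rep_len(death_day, n)
  ifelse(!is.na(death_day) & death_day < horizon, 0,
         pmax(0, horizon - stay_days))
}

#' New or progressive AKI within the endpoint window
#'
#' True when the maximum KDIGO stage over days 1..7 exceeds the stage at
#' enrollment (receipt of KRT maps to stage 3 and therefore always
#' progresses stage 0-2 patients).
#'
#' @param stages_1_7 Integer vector of daily stages for days 1..7 (or a
#'   `stage_trajectory()` slice for one patient).
#' @param enrollment_stage Stage at enrollment (0-3).
#' @return Logical scalar.
#' @export
new_or_progressive_aki <- function(stages_1_7, enrollment_stage) {
  if (is.data.frame(stages_1_7))
    stages_1_7 <- stages_1_7$stage[stages_1_7$day >= 1]
  if (length(stages_1_7) == 0) return(FALSE)
  max(stages_1_7) > enrollment_stage
}

#' Composite of KRT or death within a horizon
#'
#' @param death_day,krt_start_day Event days or `NA`; vectorized.
#' @param horizon_days Endpoint horizon (default 7).
#' @return Logical vector.
#' @export
krt_or_death <- function(death_day, krt_start_day, horizon_days = 7) {
  (!is.na(death_day) & death_day <= horizon_days) |
    (!is.na(krt_start_day) & krt_start_day <= horizon_days)
}

#' Peak serum creatinine within a horizon
#'
#' @param scr A [lab_series()] of SCr.
#' @param horizon_days Last day included (day bins `[24d, 24d+24)`).
#' @return Maximum SCr (mg/dL) over days 0..`horizon_days`, `NA` if no
#'   observation falls in the window.
#' @export
peak_scr <- function(scr, horizon_days = 7) {
  scr <- as_series(scr)
  v <- scr$value[scr$time_h < 24 * (horizon_days + 1)]
  if (length(v) == 0) return(NA_real_)
  max(v)
}

#' Safety flags: hypercalcemia and hyperphosphatemia
#'
#' Strict-threshold flags over the first 7 days after randomization:
#' hypercalcemia is serum calcium > 10.7 mg/dL, hyperphosphatemia is serum
#' phosphate > 6.0 mg/dL. Boundary values do not flag. Peak values and the
#' day of the peak are reported alongside the flags.
#'
#' @param calcium,phosphate [lab_series()] in mg/dL.
#' @param horizon_days Assessment window in days (default 7).
#' @return List with `hypercalcemia`, `hyperphosphatemia` (logical) and
#'   `ca_peak`, `ca_peak_day`, `po4_peak`, `po4_peak_day`.
#' @export
safety_flags <- function(calcium, phosphate, horizon_days = 7) {
  window_peak <- function(series) {
    s <- as_series(series)
    s <- s[s$time_h < 24 * (horizon_days + 1), , drop = FALSE]
    if (nrow(s) == 0) return(list(peak = NA_real_, day = NA_real_))
    i <- which.max(s$value)
    list(peak = s$value[i], day = hours_to_day(s$time_h[i]))
  }
  ca <- window_peak(calcium)
  po4 <- window_peak(phosphate)
  list(hypercalcemia = isTRUE(ca$peak > 10.7),
       hyperphosphatemia = isTRUE(po4$peak > 6.0),
       ca_peak = ca$peak, ca_peak_day = ca$day,
       po4_peak = po4$peak, po4_peak_day = po4$day)
}

#' Two-group binary comparison
#'
#' Fisher's exact test (two-sided by the point-probability method over the
#' hypergeometric support, the standard convention) or the chi-squared test
#' with 1 df. The continuity correction of the chi-squared test is off by
#' default, matching the large-sample test.
#'
#' @param a_events,a_n Events and size of group A.
#' @param b_events,b_n Events and size of group B.
#' @param method `"fisher"` (default) or `"chi2"`.
#' @param correct Continuity correction for `"chi2"`.
#' @return List with `p.value`, `method`, and the 2x2 `table`.
#' @export
#' @examples
#' compare_binary(0, 5, 5, 5)$p.value  # 2/252
compare_binary <- function(a_events, a_n, b_events, b_n,
                           method = c("fisher", "chi2"), correct = FALSE) {
  method <- match.arg(method)
  if (a_n <= 0 || b_n <= 0) stop_config("group sizes must be positive")
  if (a_events > a_n || b_events > b_n || a_events < 0 || b_events < 0)
    stop_config("event counts must lie in [0, n]")
  tab <- matrix(c(a_events, a_n - a_events, b_events, b_n - b_events),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("A", "B"),
                                outcome = c("event", "no_event")))
  p <- if (method == "fisher") {
    stats::fisher.test(tab)$p.value
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
  }
  list(p.value = p, method = method, table = tab)
}

#' Urinary KIM-1 normalized to urine creatinine
#'
#' Corrects the kidney-injury biomarker for urine dilution by expressing it
#' per unit of urinary creatinine.
#'
#' @param kim1 Urinary KIM-1 concentration (pg/mL); vectorized.
#' @param urine_creatinine Urinary creatinine (mg/dL); must be > 0.
#' @return `kim1 / urine_creatinine` (pg/mL per mg/dL).
#' @export
normalize_kim1 <- function(kim1, urine_creatinine) {
  if (any(is.na(urine_creatinine)) || any(urine_creatinine <= 0))
    stop_config("urine creatinine must be positive")
  kim1 / urine_creatinine
}

#' Classify enrollment vitamin D status
#'
#' Standard 25D thresholds: insufficient below 30 ng/mL, deficient below
#' 20 ng/mL, severely deficient below 10 ng/mL (nested categories).
#' Missing measurements are excluded from the denominator.
#'
#' @param levels_25d Numeric vector of enrollment 25D levels (ng/mL).
#' @return Data frame with `category`, `threshold_ng_ml`, `count`, `n`,
#'   `pct` (percent of non-missing).
#' @export
#' @examples
#' vitd_status_summary(c(5, 15, 25, 35))
vitd_status_summary <- function(levels_25d) {
  x <- levels_25d[!is.na(levels_25d)]
  n <- length(x)
  thr <- c(insufficient = 30, deficient = 20, severely_deficient = 10)
  counts <- vapply(thr, function(t) sum(x < t), numeric(1))
  data.frame(category = names(thr), threshold_ng_ml = unname(thr),
             count = unname(counts), n = n,
             pct = unname(100 * counts / n),
             stringsAsFactors = FALSE)
}
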