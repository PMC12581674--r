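#' Solve lognormal parameters from a printed median and interquartile range
#'
#' Concentration data (e.g. vitamin D metabolites) are strongly right-skewed
#' and are conventionally summarised as median \[IQR\]. For a lognormal
#' variable, `meanlog = log(median)` and the quartiles satisfy
#' `log(q3/q1) = 2 * qnorm(0.75) * sdlog`, so both parameters are identified
#' from the three printed numbers.
#'
#' @param median Median of the distribution.
#' @param q1,q3 First and third quartiles.
#' @return List with components `meanlog` and `sdlog`.
#' @export
#' @examples
#' lognormal_from_quartiles(16.1, 10.2, 25.9)
lognormal_from_quartiles <- function(median, q1, q3) {
  if (!(q1 > 0 && q1 < median && median < q3))
    stop_config("need 0 < q1 < median < q3, got (%s, %s, %s)", q1, median, q3)
  list(meanlog = log(median), sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

# Default per-arm fold-change schedules for plasma vitamin D metabolites,
# days 0..7 relative to the day-0 level. Anchors: calcifediol raises 25D
# 2-fold by day 1 and 3-fold by day 5 (held thereafter), with a modest rise
# in 1,25D (x1.5 by day 2); calcitriol raises 1,25D 2.5-fold by day 2 with
# 25D flat; placebo is flat for both. Day 0 is exactly 1 for every arm.
default_pk_multipliers <- function() {
  list(
    calcifediol = list(
      vitd_25  = c(1, 2, 2.25, 2.5, 2.75, 3, 3, 3),
      vitd_125 = c(1, 1.25, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5)
    ),
    calcitriol = list(
      vitd_25  = rep(1, 8),
      vitd_125 = c(1, 1.75, 2.5, 2.5, 2.5, 2.5, 2.5, 2.5)
    ),
    placebo = list(
      vitd_25  = rep(1, 8),
      vitd_125 = rep(1, 8)
    )
  )
}

#' Configuration for the synthetic three-arm ICU cohort generator
#'
#' Bundles every tunable of the generator with defaults calibrated to the
#' dynamics of a three-arm activated vitamin D trial in critically ill
#' adults: ~35% AKI prevalence at enrollment, per-arm 7-day death risks of
#' 7.8% / 18.0% / 12.2% and KRT risks of 2.0% / 2.0% / 8.2%
#' (calcifediol / calcitriol / placebo), lognormal baseline 25D
#' (median 16.1, IQR 10.2-25.9 ng/mL) and 1,25D (median 26.9,
#' IQR 17.5-39.1 pg/mL), fold-change metabolite kinetics per arm, and serum
#' creatinine trajectories whose baseline-adjusted mean 7-day change has
#' median ~0 and quartiles near -21.5% and +18.3%.
#'
#' @param n_per_arm Patients per arm (>= 1).
#' @param aki_prevalence Probability of KDIGO stage-1 AKI at enrollment.
#' @param death_risk_7d,krt_risk_7d Named per-arm 7-day event probabilities
#'   (names `calcifediol`, `calcitriol`, `placebo`).
#' @param death_risk_28d Named per-arm cumulative 28-day death probabilities;
#'   must dominate `death_risk_7d` elementwise.
#' @param baseline_scr_log_mean,baseline_scr_log_sd Lognormal parameters of
#'   enrollment serum creatinine (mg/dL).
#' @param scr_change_q25,scr_change_q75 Calibration quartiles (percent) of the
#'   per-patient baseline-adjusted mean SCr change over days 1-7.
#' @param scr_drift_by_state Mean latent drift (%/day) added per enrollment
#'   state, named `aki` and `no_aki`.
#' @param scr_noise_sd Daily multiplicative SCr noise, percent of the current
#'   value.
#' @param vitd25_params,vitd125_params Lognormal parameters (lists with
#'   `meanlog`, `sdlog`) of baseline 25D (ng/mL) and 1,25D (pg/mL).
#' @param pk_multipliers Per-arm fold-change schedules, days 0..7, as returned
#'   by [default_pk_multipliers()]; day 0 must equal 1 everywhere.
#' @param pk_cv Coefficient of variation of the multiplicative (mean-one
#'   lognormal) noise around the metabolite schedule.
#' @param ca_mean,ca_sd,po4_mean,po4_sd Population means and between-patient
#'   SDs of serum calcium and phosphate (mg/dL).
#' @param ca_day_sd,po4_day_sd Within-patient day-to-day SDs (mg/dL).
#' @param mineral_offsets Named list of per-arm additive offsets, each a
#'   vector `c(ca = ..., po4 = ...)` in mg/dL.
#' @param uop_log_mean,uop_log_sd Lognormal parameters of the patient-level
#'   mean urine output (mL/kg/h).
#' @param uop_hour_sd Hourly additive noise SD (mL/kg/h).
#' @param icu_los_log_mean,icu_los_log_sd Lognormal parameters of ICU length
#'   of stay among survivors (days).
#' @param hosp_extra_log_mean,hosp_extra_log_sd Lognormal parameters of the
#'   post-ICU hospital stay among survivors (days).
#' @param horizon_days Lab simulation horizon in days (>= 7).
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_per_arm = 50,
                          aki_prevalence = 0.35,
                          death_risk_7d = c(calcifediol = 0.078,
                                            calcitriol = 0.180,
                                            placebo = 0.122),
                          krt_risk_7d = c(calcifediol = 0.020,
                                          calcitriol = 0.020,
                                          placebo = 0.082),
                          death_risk_28d = death_risk_7d + 0.08,
                          baseline_scr_log_mean = log(1.1),
                          baseline_scr_log_sd = 0.35,
                          scr_change_q25 = -21.5,
                          scr_change_q75 = 18.3,
                          scr_drift_by_state = c(aki = 0, no_aki = 0),
                          scr_noise_sd = 5,
                          vitd25_params = lognormal_from_quartiles(16.1, 10.2, 25.9),
                          vitd125_params = lognormal_from_quartiles(26.9, 17.5, 39.1),
                          pk_multipliers = default_pk_multipliers(),
                          pk_cv = 0.15,
                          ca_mean = 8.6, ca_sd = 0.6, ca_day_sd = 0.4,
                          po4_mean = 3.8, po4_sd = 0.9, po4_day_sd = 0.5,
                          mineral_offsets = list(
                            calcifediol = c(ca = 0.2, po4 = 0.3),
                            calcitriol = c(ca = 0.4, po4 = 0.8),
                            placebo = c(ca = 0, po4 = 0)),
                          uop_log_mean = log(1.0), uop_log_sd = 0.5,
                          uop_hour_sd = 0.15,
                          icu_los_log_mean = log(6), icu_los_log_sd = 0.6,
                          hosp_extra_log_mean = log(8), hosp_extra_log_sd = 0.7,
                          horizon_days = 7) {
  if (!is.numeric(n_per_arm) || n_per_arm < 1 || n_per_arm != round(n_per_arm))
    stop_config("n_per_arm must be a positive integer")
  if (horizon_days < 7) stop_config("horizon_days must be >= 7")
  check_prob(aki_prevalence, "aki_prevalence")
  death_risk_7d <- check_arm_vec(death_risk_7d, "death_risk_7d")
  krt_risk_7d <- check_arm_vec(krt_risk_7d, "krt_risk_7d")
  death_risk_28d <- check_arm_vec(death_risk_28d, "death_risk_28d")
  check_prob(death_risk_7d, "death_risk_7d")
  check_prob(krt_risk_7d, "krt_risk_7d")
  check_prob(death_risk_28d, "death_risk_28d")
  if (any(death_risk_28d < death_risk_7d))
    stop_config("death_risk_28d must be >= death_risk_7d for every arm")
  if (!setequal(names(pk_multipliers), ARMS))
    stop_config("pk_multipliers must cover arms %s", paste(ARMS, collapse = ", "))
  for (arm in ARMS) for (an in c("vitd_25", "vitd_125")) {
    sched <- pk_multipliers[[arm]][[an]]
    if (length(sched) < horizon_days + 1)
      stop_config("pk schedule for %s/%s must cover days 0..%d", arm, an, horizon_days)
    if (sched[1] != 1)
      stop_config("pk schedule day-0 multiplier must be exactly 1 (%s/%s)", arm, an)
    if (any(sched <= 0)) stop_config("pk multipliers must be positive")
  }
  if (scr_change_q25 >= 0 || scr_change_q75 <= 0)
    stop_config("scr change calibration quartiles must straddle zero")
  if (!setequal(names(scr_drift_by_state), c("aki", "no_aki")))
    stop_config("scr_drift_by_state must be named aki, no_aki")
  if (scr_noise_sd < 0 || pk_cv < 0) stop_config("noise parameters must be >= 0")
  cfg <- list(
    n_per_arm = as.integer(n_per_arm), aki_prevalence = aki_prevalence,
    death_risk_7d = death_risk_7d, krt_risk_7d = krt_risk_7d,
    death_risk_28d = death_risk_28d,
    baseline_scr_log_mean = baseline_scr_log_mean,
    baseline_scr_log_sd = baseline_scr_log_sd,
    scr_change_q25 = scr_change_q25, scr_change_q75 = scr_change_q75,
    scr_drift_by_state = scr_drift_by_state[c("aki", "no_aki")],
    scr_noise_sd = scr_noise_sd,
    vitd25_params = vitd25_params, vitd125_params = vitd125_params,
    pk_multipliers = pk_multipliers[ARMS], pk_cv = pk_cv,
    ca_mean = ca_mean, ca_sd = ca_sd, ca_day_sd = ca_day_sd,
    po4_mean = po4_mean, po4_sd = po4_sd, po4_day_sd = po4_day_sd,
    mineral_offsets = mineral_offsets[ARMS],
    uop_log_mean = uop_log_mean, uop_log_sd = uop_log_sd,
    uop_hour_sd = uop_hour_sd,
    icu_los_log_mean = icu_los_log_mean, icu_los_log_sd = icu_los_log_sd,
    hosp_extra_log_mean = hosp_extra_log_mean,
    hosp_extra_log_sd = hosp_extra_log_sd,
    horizon_days = as.integer(horizon_days))
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic ICU trial cohort configuration\n")
  cat(sprintf("  %d patients/arm, AKI prevalence %.0f%%, horizon %d days\n",
              x$n_per_arm, 100 * x$aki_prevalence, x$horizon_days))
  cat(sprintf("  7-day death risk: %s\n",
              paste(sprintf("%s %.1f%%", ARMS, 100 * x$death_risk_7d), collapse = ", ")))
  cat(sprintf("  7-day KRT risk:   %s\n",
              paste(sprintf("%s %.1f%%", ARMS, 100 * x$krt_risk_7d), collapse = ", ")))
  invisible(x)
}

# Invert the mean-change map: find the daily geometric drift rate r such that
# the mean of (1+r)^d - 1 over days 1..horizon equals target_pct / 100.
drift_from_target_change <- function(target_pct, horizon_days = 7) {
  f <- function(r) mean((1 + r)^(seq_len(horizon_days))) - 1 - target_pct / 100
  stats::uniroot(f, c(-0.999, 50), tol = 1e-10)$root
}

# Draw per-patient target mean changes from an asymmetric two-sided
# half-normal whose quartiles equal the calibration quartiles and whose
# median is zero.
draw_target_changes <- function(n, q25, q75) {
  side <- stats::runif(n) < 0.5
  scale_lo <- abs(q25) / stats::qnorm(0.75)
  scale_hi <- q75 / stats::qnorm(0.75)
  z <- abs(stats::rnorm(n))
  ifelse(side, -scale_lo * z, scale_hi * z)
}
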