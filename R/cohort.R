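#' Stratified permuted-block randomization
#'
#' Allocates patients 1:1:1 to `calcifediol`, `calcitriol`, or `placebo`
#' using permuted blocks of 3, stratified by the presence of AKI at
#' enrollment. Within each stratum, consecutive enrollees fill shuffled
#' blocks that contain each arm exactly once, so arm counts within a stratum
#' never differ by more than one.
#'
#' @param aki_at_enrollment Logical vector, one stratum flag per patient in
#'   enrollment order.
#' @param seed Optional integer seed; when supplied the assignment is
#'   reproducible.
#' @return Character vector of arm labels, one per patient, in input order.
#' @export
#' @examples
#' table(assign_randomization(rep(c(TRUE, FALSE), each = 6), seed = 1))
assign_randomization <- function(aki_at_enrollment, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(aki_at_enrollment)
  if (n == 0) return(character(0))
  if (any(is.na(aki_at_enrollment)))
    stop_config("stratum flags must be non-missing")
  arms <- character(n)
  for (stratum in unique(aki_at_enrollment)) {
    idx <- which(aki_at_enrollment == stratum)
    n_blocks <- ceiling(length(idx) / 3)
    blocks <- unlist(lapply(seq_len(n_blocks), function(i) sample(ARMS)))
    arms[idx] <- blocks[seq_along(idx)]
  }
  arms
}

#' Simulate a serum creatinine trajectory
#'
#' Daily SCr for days 0..`horizon_days`, generated as multiplicative
#' lognormal noise around a latent geometric drift:
#' `SCr_d = baseline * (1 + drift)^d * eps_d`, with `eps_d` mean-one
#' lognormal at the configured daily noise SD. Observations after the day of
#' death are censored.
#'
#' @param baseline_scr Enrollment SCr in mg/dL (> 0).
#' @param drift_pct_per_day Latent drift in percent per day.
#' @param noise_sd_pct Daily multiplicative noise, percent of current value.
#' @param horizon_days Last simulated day.
#' @param death_day Day of death (labs stop after this day) or `NA`.
#' @return A [lab_series()] of daily SCr (mg/dL), observed at hours
#'   `0, 24, 48, ...`.
#' @export
simulate_scr_trajectory <- function(baseline_scr, drift_pct_per_day = 0,
                                    noise_sd_pct = 5, horizon_days = 7,
                                    death_day = NA) {
  if (!is.finite(baseline_scr) || baseline_scr <= 0)
    stop_config("baseline_scr must be positive")
  days <- 0:horizon_days
  if (!is.na(death_day)) days <- days[days <= death_day]
  g <- (1 + drift_pct_per_day / 100)^days
  noise <- mean_one_lognormal(length(days), noise_sd_pct / 100)
  noise[1] <- 1  # day 0 is the measured baseline
  lab_series("scr", "mg/dL", day_to_hours(days), baseline_scr * g * noise)
}

# Mean-one multiplicative lognormal noise at coefficient of variation cv.
mean_one_lognormal <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate plasma vitamin D metabolite kinetics
#'
#' Daily 25D and 1,25D levels for days 0..`horizon_days` as the arm's
#' deterministic fold-change schedule times the patient's baseline, with
#' multiplicative mean-one lognormal noise (CV `pk_cv`). With the default
#' calibration the calcifediol arm doubles 25D by day 1 and triples it by
#' day 5, the calcitriol arm raises 1,25D 2.5-fold by day 2, and the placebo
#' arm stays flat for both metabolites.
#'
#' @param arm Arm label (`"calcifediol"`, `"calcitriol"`, or `"placebo"`).
#' @param baseline_25d Baseline 25D in ng/mL (> 0).
#' @param baseline_125d Baseline 1,25D in pg/mL (> 0).
#' @param config A [cohort_config()].
#' @param death_day Day of death (labs stop after this day) or `NA`.
#' @return List with elements `vitd_25` and `vitd_125`, each a [lab_series()].
#' @export
#' @examples
#' cfg <- cohort_config(pk_cv = 0)  # noise-free schedules
#' pk <- simulate_vitd_pk("calcifediol", 10, 20, cfg)
#' pk$vitd_25$value[6] / pk$vitd_25$value[1]  # 3-fold by day 5
simulate_vitd_pk <- function(arm, baseline_25d, baseline_125d, config,
                             death_day = NA) {
  if (!arm %in% ARMS)
    stop_config("unknown arm '%s' (expected one of %s)", arm,
                paste(ARMS, collapse = ", "))
  if (baseline_25d <= 0 || baseline_125d <= 0)
    stop_config("metabolite baselines must be positive")
  days <- 0:config$horizon_days
  if (!is.na(death_day)) days <- days[days <= death_day]
  sched <- config$pk_multipliers[[arm]]
  series_for <- function(analyte, unit, baseline) {
    mult <- sched[[analyte]][days + 1]
    noise <- mean_one_lognormal(length(days), config$pk_cv)
    lab_series(analyte, unit, day_to_hours(days), baseline * mult * noise)
  }
  list(vitd_25 = series_for("vitd_25", "ng/mL", baseline_25d),
       vitd_125 = series_for("vitd_125", "pg/mL", baseline_125d))
}

#' Simulate death and KRT events for one patient
#'
#' Death within 7 days and KRT within 7 days are independent Bernoulli draws
#' at the arm-specific configured risks; event days are uniform over days
#' 0..7. Patients surviving day 7 may still die by day 28 (cumulative risk
#' `death_risk_28d`), with the later death day uniform over days 8..28.
#' Death precedence over KRT is enforced by the endpoint tiers downstream,
#' not here. ICU and hospital stays are drawn consistent with the events
#' (censored at the death day for decedents).
#'
#' @param arm Arm label.
#' @param config A [cohort_config()].
#' @return List with `death_day`, `krt_start_day` (day index or `NA`),
#'   `icu_days`, `hospital_days`.
#' @export
simulate_events <- function(arm, config) {
  if (!arm %in% ARMS) stop_config("unknown arm '%s'", arm)
  p7 <- config$death_risk_7d[[arm]]
  p28 <- config$death_risk_28d[[arm]]
  death_day <- NA_real_
  if (stats::runif(1) < p7) {
    death_day <- sample(0:7, 1)
  } else if (p7 < 1 && stats::runif(1) < (p28 - p7) / (1 - p7)) {
    death_day <- sample(8:28, 1)
  }
  krt_start_day <- if (stats::runif(1) < config$krt_risk_7d[[arm]])
    sample(0:7, 1) else NA_real_
  icu_days <- 1 + stats::rlnorm(1, config$icu_los_log_mean, config$icu_los_log_sd)
  hospital_days <- icu_days +
    stats::rlnorm(1, config$hosp_extra_log_mean, config$hosp_extra_log_sd)
  if (!is.na(death_day)) {
    icu_days <- min(icu_days, death_day + 1)
    hospital_days <- min(hospital_days, death_day + 1)
  }
  list(death_day = death_day, krt_start_day = krt_start_day,
       icu_days = round(icu_days), hospital_days = round(hospital_days))
}

#' Simulate serum calcium and phosphate series
#'
#' Daily values for days 0..`horizon_days` with a patient-level random
#' intercept, day-to-day noise, and additive per-arm offsets (the calcitriol
#' offsets are the largest, so that arm runs the highest calcium and
#' phosphate; hypercalcemia above 10.7 mg/dL remains a rare tail event).
#'
#' @inheritParams simulate_vitd_pk
#' @return List with `calcium` and `phosphate` [lab_series()] (mg/dL).
#' @export
simulate_mineral_labs <- function(arm, config, death_day = NA) {
  if (!arm %in% ARMS) stop_config("unknown arm '%s'", arm)
  days <- 0:config$horizon_days
  if (!is.na(death_day)) days <- days[days <= death_day]
  off <- config$mineral_offsets[[arm]]
  one <- function(analyte, mean, sd_pat, sd_day, offset, floor) {
    level <- stats::rnorm(1, mean + offset, sd_pat)
    vals <- pmax(floor, level + stats::rnorm(length(days), 0, sd_day))
    lab_series(analyte, "mg/dL", day_to_hours(days), vals)
  }
  list(calcium = one("calcium", config$ca_mean, config$ca_sd,
                     config$ca_day_sd, off[["ca"]], 5),
       phosphate = one("phosphate", config$po4_mean, config$po4_sd,
                       config$po4_day_sd, off[["po4"]], 0.5))
}

#' Simulate hourly urine output
#'
#' Hourly urine output (mL/kg/h) for the full horizon, as per-hour means
#' around a lognormal patient-level mean; sufficient resolution for the
#' KDIGO 6-hour and 12-hour oliguria run-length rules.
#'
#' @inheritParams simulate_vitd_pk
#' @return A [lab_series()] at 1-hour resolution (mL/kg/h).
#' @export
simulate_uop <- function(config, death_day = NA) {
  last_h <- 24 * (config$horizon_days + 1) - 1
  hours <- 0:last_h
  if (!is.na(death_day)) hours <- hours[hours <= day_to_hours(death_day) + 23]
  m <- stats::rlnorm(1, config$uop_log_mean, config$uop_log_sd)
  vals <- pmax(0.01, m + stats::rnorm(length(hours), 0, config$uop_hour_sd))
  lab_series("uop", "mL/kg/h", hours, vals)
}

#' Generate a randomized synthetic three-arm ICU cohort
#'
#' Draws `3 * n_per_arm` patients with enrollment covariates, stratified
#' permuted-block arm assignment, death/KRT events, and daily (hourly for
#' urine output) laboratory series per the configured calibration. All
#' randomness flows from `seed`, so identical `(config, seed)` reproduce the
#' cohort field-for-field.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return An object of class `aki_cohort`: a list with
#'   \describe{
#'     \item{patients}{one row per patient: `patient_id`, `arm`, `age`,
#'       `sex`, `icu_type`, `apache2`, `septic_shock`, `aki_on_enrollment`,
#'       `weight`, `baseline_scr`, `egfr`, `death_day`, `krt_start_day`,
#'       `icu_days`, `hospital_days`}
#'     \item{labs}{long format: `patient_id`, `analyte`, `time_h`, `value`,
#'       `unit`}
#'     \item{config, seed}{the generating configuration and seed}
#'   }
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_arm = 5), seed = 1)
#' table(cohort$patients$arm)
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- 3L * config$n_per_arm

  aki <- stats::runif(n) < config$aki_prevalence
  arm <- assign_randomization(aki)

  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    arm = arm,
    age = pmin(95, pmax(18, round(stats::rnorm(n, 62, 15)))),
    sex = sample(c("F", "M"), n, replace = TRUE),
    icu_type = sample(c("medical", "surgical"), n, replace = TRUE,
                      prob = c(0.6, 0.4)),
    apache2 = pmin(50, pmax(2, round(stats::rnorm(n, 24, 7)))),
    septic_shock = stats::runif(n) < 0.7,
    aki_on_enrollment = aki,
    weight = round(stats::rlnorm(n, log(80), 0.22), 1),
    baseline_scr = round(stats::rlnorm(n, config$baseline_scr_log_mean,
                                       config$baseline_scr_log_sd), 2),
    egfr = pmax(16, round(stats::rnorm(n, 70, 25))),
    stringsAsFactors = FALSE)

  drift_target <- draw_target_changes(n, config$scr_change_q25,
                                      config$scr_change_q75)
  state_drift <- ifelse(aki, config$scr_drift_by_state[["aki"]],
                        config$scr_drift_by_state[["no_aki"]])

  baseline_25d <- stats::rlnorm(n, config$vitd25_params$meanlog,
                                config$vitd25_params$sdlog)
  baseline_125d <- stats::rlnorm(n, config$vitd125_params$meanlog,
                                 config$vitd125_params$sdlog)

  events <- vector("list", n)
  labs <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- simulate_events(arm[i], config)
    events[[i]] <- ev
    dd7 <- if (!is.na(ev$death_day) && ev$death_day <= config$horizon_days)
      ev$death_day else NA
    drift <- state_drift[i] +
      100 * drift_from_target_change(drift_target[i], config$horizon_days)
    scr <- simulate_scr_trajectory(patients$baseline_scr[i], drift,
                                   config$scr_noise_sd, config$horizon_days,
                                   death_day = dd7)
    pk <- simulate_vitd_pk(arm[i], baseline_25d[i], baseline_125d[i],
                           config, death_day = dd7)
    minerals <- simulate_mineral_labs(arm[i], config, death_day = dd7)
    uop <- simulate_uop(config, death_day = dd7)
    labs[[i]] <- do.call(rbind, lapply(
      list(scr, pk$vitd_25, pk$vitd_125, minerals$calcium,
           minerals$phosphate, uop),
      function(s) data.frame(patient_id = patients$patient_id[i],
                             analyte = attr(s, "analyte"),
                             time_h = s$time_h, value = s$value,
                             unit = attr(s, "unit"),
                             stringsAsFactors = FALSE)))
  }
  patients$death_day <- vapply(events, function(e) e$death_day, numeric(1))
  patients$krt_start_day <- vapply(events, function(e) e$krt_start_day,
                                   numeric(1))
  patients$icu_days <- vapply(events, function(e) e$icu_days, numeric(1))
  patients$hospital_days <- vapply(events, function(e) e$hospital_days,
                                   numeric(1))

  out <- list(patients = patients, labs = do.call(rbind, labs),
              config = config, seed = seed)
  class(out) <- "aki_cohort"
  out
}

#' @export
print.aki_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ICU trial cohort: %d patients (seed %s)\n",
              nrow(x$patients), format(x$seed)))
  print(table(x$patients$arm))
  invisible(x)
}

#' Write / read a cohort as delimited files
#'
#' `write_cohort()` stores `patients.csv` (one row per patient) and
#' `labs.csv` (long format) under `dir`; `read_cohort()` restores a cohort
#' object from such a directory and validates it.
#'
#' @param cohort An `aki_cohort`.
#' @param dir Directory (created if absent).
#' @return `write_cohort()` the file paths invisibly; `read_cohort()` an
#'   `aki_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "aki_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             labs = file.path(dir, "labs.csv"))
  utils::write.csv(cohort$patients, paths["patients"], row.names = FALSE)
  utils::write.csv(cohort$labs, paths["labs"], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE)
  labs <- utils::read.csv(file.path(dir, "labs.csv"), stringsAsFactors = FALSE)
  out <- list(patients = patients, labs = labs, config = NULL, seed = NULL)
  class(out) <- "aki_cohort"
  validate_cohort(out)
  out
}

#' Validate a cohort's schema and invariants
#'
#' Checks column presence, positivity of concentrations, event-day ranges,
#' and that no lab observation postdates the patient's death. Violations
#' raise an itemized error naming the offending rows.
#'
#' @param cohort An `aki_cohort` (or a list with `patients`/`labs`).
#' @return The cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  req_p <- c("patient_id", "arm", "aki_on_enrollment", "weight",
             "baseline_scr", "death_day", "krt_start_day",
             "icu_days", "hospital_days")
  req_l <- c("patient_id", "analyte", "time_h", "value", "unit")
  problems <- character(0)
  missing_p <- setdiff(req_p, names(cohort$patients))
  if (length(missing_p))
    problems <- c(problems, sprintf("patients: missing columns %s",
                                    paste(missing_p, collapse = ", ")))
  missing_l <- setdiff(req_l, names(cohort$labs))
  if (length(missing_l))
    problems <- c(problems, sprintf("labs: missing columns %s",
                                    paste(missing_l, collapse = ", ")))
  if (!length(problems)) {
    bad_arm <- !cohort$patients$arm %in% ARMS
    if (any(bad_arm))
      problems <- c(problems, sprintf("patients: unknown arm in rows %s",
                                      paste(which(bad_arm), collapse = ", ")))
    bad_val <- !is.finite(cohort$labs$value) | cohort$labs$value <= 0
    if (any(bad_val))
      problems <- c(problems, sprintf("labs: nonpositive value in rows %s",
                                      paste(utils::head(which(bad_val), 10),
                                            collapse = ", ")))
    bad_scr <- !is.finite(cohort$patients$baseline_scr) |
      cohort$patients$baseline_scr <= 0
    if (any(bad_scr))
      problems <- c(problems, sprintf("patients: nonpositive baseline_scr rows %s",
                                      paste(which(bad_scr), collapse = ", ")))
    dd <- cohort$patients$death_day
    death_at <- stats::setNames(dd, cohort$patients$patient_id)
    lab_dd <- death_at[cohort$labs$patient_id]
    after <- !is.na(lab_dd) & cohort$labs$time_h >= 24 * (lab_dd + 1)
    if (any(after))
      problems <- c(problems, sprintf("labs: observation after death in rows %s",
                                      paste(utils::head(which(after), 10),
                                            collapse = ", ")))
  }
  if (length(problems))
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(cohort)
}
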