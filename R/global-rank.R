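#' Baseline-adjusted mean percent change in serum creatinine
#'
#' The kidney-injury tier of the hierarchical composite: the mean over
#' eligible daily values of `100 * (SCr_d - baseline) / baseline`, taken
#' over days 1..`horizon_days`. Day 0 is the baseline itself and is not
#' averaged. Values observed at or after the start of kidney replacement
#' therapy are excluded (KRT patients sit in the middle tier regardless, and
#' dialysis makes later creatinine uninterpretable as injury).
#'
#' @param scr A [lab_series()] of SCr (mg/dL).
#' @param baseline Enrollment SCr in mg/dL (> 0).
#' @param horizon_days Endpoint horizon (default 7).
#' @param krt_start_day Day KRT started, or `NA`.
#' @return Mean percent change, or `NA` with attribute
#'   `unevaluable = TRUE` when no eligible post-baseline observation exists.
#' @export
#' @examples
#' s <- lab_series("scr", "mg/dL", c(0, 24, 48), c(1.0, 1.2, 1.4))
#' baseline_adjusted_mean_change(s, baseline = 1.0)  # +30
baseline_adjusted_mean_change <- function(scr, baseline, horizon_days = 7,
                                          krt_start_day = NA) {
  if (!is.finite(baseline) || baseline <= 0)
    stop_config("baseline must be positive")
  scr <- as_series(scr)
  lo <- day_to_hours(1)
  hi <- day_to_hours(horizon_days) + 24  # day bins are [24d, 24d+24)
  keep <- scr$time_h >= lo & scr$time_h < hi
  if (!is.na(krt_start_day))
    keep <- keep & scr$time_h < day_to_hours(krt_start_day)
  vals <- scr$value[keep]
  if (length(vals) == 0) {
    out <- NA_real_
    attr(out, "unevaluable") <- TRUE
    return(out)
  }
  mean(100 * (vals - baseline) / baseline)
}

#' Build per-patient hierarchical endpoint inputs from a cohort
#'
#' Reduces each patient to their endpoint tier within the 7-day window:
#' death (worst), then KRT among survivors, then the baseline-adjusted mean
#' SCr change among event-free patients. Death takes precedence when both
#' events occur. Survivors with no post-baseline creatinine are assigned a
#' change of 0% and flagged `unevaluable` (missing endpoint data are not
#' imputed; the flag supports sensitivity analyses), with a warning.
#'
#' @param cohort An `aki_cohort`.
#' @param horizon_days Endpoint horizon (default 7).
#' @return Data frame with `patient_id`, `arm`, `died_7d`, `krt_7d`, `tier`
#'   (`"death"`, `"krt"`, `"scr"`), `scr_mean_change` (`NA` off the SCr
#'   tier), `unevaluable`.
#' @export
global_rank_inputs <- function(cohort, horizon_days = 7) {
  p <- cohort$patients
  died <- !is.na(p$death_day) & p$death_day <= horizon_days
  krt <- !is.na(p$krt_start_day) & p$krt_start_day <= horizon_days & !died
  tier <- ifelse(died, "death", ifelse(krt, "krt", "scr"))
  change <- rep(NA_real_, nrow(p))
  unevaluable <- rep(FALSE, nrow(p))
  for (i in which(tier == "scr")) {
    scr <- labs_for(cohort$labs, p$patient_id[i], "scr")
    ch <- baseline_adjusted_mean_change(scr, p$baseline_scr[i], horizon_days,
                                        p$krt_start_day[i])
    if (is.na(ch)) {
      change[i] <- 0
      unevaluable[i] <- TRUE
    } else {
      change[i] <- ch
    }
  }
  if (any(unevaluable))
    warning(sprintf("%d survivor(s) had no post-baseline SCr; assigned 0%% change and flagged",
                    sum(unevaluable)), call. = FALSE)
  data.frame(patient_id = p$patient_id, arm = p$arm, died_7d = died,
             krt_7d = krt, tier = tier, scr_mean_change = change,
             unevaluable = unevaluable, stringsAsFactors = FALSE)
}

# Numeric tier code: 1 = SCr (best) < 2 = KRT < 3 = death (worst).
tier_code <- function(tier) {
  unname(c(scr = 1, krt = 2, death = 3)[tier])
}

# Midranks of the total preorder (tier, value): rank 1 = best outcome.
# Event-tier patients are internally tied; SCr-tier patients order by
# ascending mean change.
midranks <- function(tier_num, value) {
  n <- length(tier_num)
  value <- ifelse(tier_num > 1, 0, value)  # within-tier value only on tier 1
  o <- order(tier_num, value)
  t_s <- tier_num[o]; v_s <- value[o]
  new_grp <- c(TRUE, t_s[-1] != t_s[-n] | v_s[-1] != v_s[-n])
  g <- cumsum(new_grp)
  mid <- stats::ave(seq_len(n), g, FUN = mean)
  out <- numeric(n)
  out[o] <- mid
  out
}

#' Assign global ranks for the hierarchical composite endpoint
#'
#' Ranks all patients jointly: the death tier shares the worst midrank
#' block, the KRT tier the next, and event-free patients are ordered by
#' ascending baseline-adjusted mean SCr change (a larger rise ranks worse).
#' Ties receive midranks, so the ranks always sum to `n(n+1)/2`.
#'
#' @param inputs Data frame as produced by [global_rank_inputs()] (columns
#'   `patient_id`, `tier`, `scr_mean_change`).
#' @return The input data frame with a `rank` column appended (1 = best).
#' @export
#' @examples
#' x <- data.frame(patient_id = LETTERS[1:5],
#'                 tier = c("death", "krt", "scr", "scr", "scr"),
#'                 scr_mean_change = c(NA, NA, 40, 0, -20))
#' assign_global_ranks(x)$rank  # 5, 4, 3, 2, 1
assign_global_ranks <- function(inputs) {
  if (anyDuplicated(inputs$patient_id))
    stop_config("duplicate patient ids in rank inputs")
  if (!all(inputs$tier %in% c("death", "krt", "scr")))
    stop_config("tier must be death, krt, or scr")
  if (any(inputs$tier == "scr" & is.na(inputs$scr_mean_change)))
    stop_config("SCr-tier patients need a mean change value")
  inputs$rank <- midranks(tier_code(inputs$tier), inputs$scr_mean_change)
  inputs
}

#' Compare two arms on the hierarchical composite endpoint
#'
#' Recomputes midranks on the pooled two-arm set (never reusing ranks from
#' a three-arm ranking) and applies the Wilcoxon rank-sum test via
#' [rank_sum_test()]: exact enumeration for small pooled sizes, the
#' tie-corrected moment approximation otherwise. Two-sided.
#'
#' @param inputs_a,inputs_b Data frames of endpoint inputs (as from
#'   [global_rank_inputs()]) for the two arms.
#' @param exact_limit,refine Passed to [rank_sum_test()].
#' @return A `rank_sum_test` result; the statistic is the rank sum of the
#'   first arm.
#' @export
compare_arms <- function(inputs_a, inputs_b, exact_limit = 16, refine = TRUE) {
  if (nrow(inputs_a) == 0 || nrow(inputs_b) == 0)
    stop_config("both arms must be nonempty")
  pooled_tier <- tier_code(c(inputs_a$tier, inputs_b$tier))
  pooled_val <- c(inputs_a$scr_mean_change, inputs_b$scr_mean_change)
  key <- midranks(pooled_tier, pooled_val)
  rank_sum_test(key[seq_len(nrow(inputs_a))],
                key[nrow(inputs_a) + seq_len(nrow(inputs_b))],
                exact_limit = exact_limit, refine = refine)
}

# The seven prespecified enrollment subgroups; median splits are computed
# on the full enrolled cohort.
subgroup_definitions <- function(cohort) {
  p <- cohort$patients
  med_apache <- stats::median(p$apache2, na.rm = TRUE)
  d0 <- cohort$labs[cohort$labs$analyte == "vitd_25" &
                      cohort$labs$time_h == 0, c("patient_id", "value")]
  vitd0 <- d0$value[match(p$patient_id, d0$patient_id)]
  med_vitd <- stats::median(vitd0, na.rm = TRUE)
  list(
    age = ifelse(p$age < 65, "<65", ">=65"),
    sex = p$sex,
    aki_on_enrollment = ifelse(p$aki_on_enrollment, "present", "absent"),
    icu_type = p$icu_type,
    apache2 = ifelse(p$apache2 <= med_apache, "<=median", ">median"),
    septic_shock = ifelse(p$septic_shock, "present", "absent"),
    vitd_25 = ifelse(is.na(vitd0), NA,
                     ifelse(vitd0 <= med_vitd, "<=median", ">median")))
}

#' Subgroup analyses of the primary endpoint
#'
#' Repeats the two-arm global-rank comparison (each active arm versus
#' placebo) within each level of the seven prespecified enrollment
#' subgroups: age (< 65 vs >= 65), sex, AKI on enrollment, ICU type,
#' APACHE II (median split), septic shock, and baseline 25D (median split).
#' Ranks are recomputed within each subgroup. A level in which either arm
#' is empty is reported as not estimable rather than raising an error.
#'
#' @param cohort An `aki_cohort`.
#' @param inputs Optional precomputed [global_rank_inputs()] table.
#' @param horizon_days Endpoint horizon.
#' @return Data frame with one row per (subgroup, level, contrast):
#'   `subgroup`, `level`, `contrast`, `n_active`, `n_placebo`, `statistic`,
#'   `p_value`, `method` (`"not_estimable"` for empty cells).
#' @export
subgroup_analysis <- function(cohort, inputs = NULL, horizon_days = 7) {
  if (is.null(inputs)) inputs <- global_rank_inputs(cohort, horizon_days)
  defs <- subgroup_definitions(cohort)
  idx <- match(inputs$patient_id, cohort$patients$patient_id)
  rows <- list()
  for (sg in names(defs)) {
    lev_vec <- defs[[sg]][idx]
    for (lev in sort(unique(stats::na.omit(lev_vec)))) {
      sub <- inputs[!is.na(lev_vec) & lev_vec == lev, , drop = FALSE]
      for (active in c("calcifediol", "calcitriol")) {
        a <- sub[sub$arm == active, , drop = FALSE]
        b <- sub[sub$arm == "placebo", , drop = FALSE]
        if (nrow(a) == 0 || nrow(b) == 0) {
          rows[[length(rows) + 1]] <- data.frame(
            subgroup = sg, level = lev,
            contrast = paste0(active, "_vs_placebo"),
            n_active = nrow(a), n_placebo = nrow(b),
            statistic = NA_real_, p_value = NA_real_,
            method = "not_estimable", stringsAsFactors = FALSE)
        } else {
          ct <- compare_arms(a, b)
          rows[[length(rows) + 1]] <- data.frame(
            subgroup = sg, level = lev,
            contrast = paste0(active, "_vs_placebo"),
            n_active = nrow(a), n_placebo = nrow(b),
            statistic = ct$statistic, p_value = ct$p.value,
            method = ct$method, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
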