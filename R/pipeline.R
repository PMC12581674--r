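summ_med_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return("-")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.2f [%.2f, %.2f]", q[2], q[1], q[3])
}

#' Arm-level outcome table with contrast p-values
#'
#' Summarises the trial's endpoints per arm — 7-day deaths, KRT, new or
#' progressive AKI, the KRT-or-death composite, peak SCr, ICU- and
#' hospital-free days, 28-day mortality, hypercalcemia and
#' hyperphosphatemia — and computes each active-versus-placebo contrast:
#' Fisher's exact test for binary endpoints, the rank-sum test for
#' continuous ones.
#'
#' @param cohort An `aki_cohort`.
#' @param stages Optional precomputed [stage_trajectory()] table.
#' @param horizon_days Endpoint horizon for the 7-day outcomes.
#' @return Data frame with one row per endpoint: per-arm summaries,
#'   `p_calcifediol`, `p_calcitriol`, and `test`.
#' @export
outcome_table <- function(cohort, stages = NULL, horizon_days = 7) {
  p <- cohort$patients
  if (is.null(stages)) stages <- stage_trajectory(cohort, horizon_days)

  died7 <- !is.na(p$death_day) & p$death_day <= horizon_days
  krt7 <- !is.na(p$krt_start_day) & p$krt_start_day <= horizon_days
  died28 <- !is.na(p$death_day) & p$death_day < 28
  composite <- krt_or_death(p$death_day, p$krt_start_day, horizon_days)

  npa <- logical(nrow(p))
  peak <- numeric(nrow(p))
  hyperca <- logical(nrow(p))
  hyperpo4 <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    pid <- p$patient_id[i]
    st <- stages[stages$patient_id == pid, , drop = FALSE]
    npa[i] <- new_or_progressive_aki(st, st$stage[st$day == 0])
    scr <- labs_for(cohort$labs, pid, "scr")
    peak[i] <- if (nrow(scr)) peak_scr(scr, horizon_days) else NA_real_
    fl <- safety_flags(labs_for(cohort$labs, pid, "calcium"),
                       labs_for(cohort$labs, pid, "phosphate"), horizon_days)
    hyperca[i] <- fl$hypercalcemia
    hyperpo4[i] <- fl$hyperphosphatemia
  }
  icu_free <- free_days(p$icu_days, p$death_day)
  hosp_free <- free_days(p$hospital_days, p$death_day)

  arm_idx <- lapply(ARMS, function(a) p$arm == a)
  names(arm_idx) <- ARMS

  binary_row <- function(endpoint, flag) {
    counts <- vapply(ARMS, function(a) sum(flag[arm_idx[[a]]]), numeric(1))
    ns <- vapply(ARMS, function(a) sum(arm_idx[[a]]), numeric(1))
    pvals <- vapply(c("calcifediol", "calcitriol"), function(a)
      compare_binary(counts[[a]], ns[[a]], counts[["placebo"]],
                     ns[["placebo"]])$p.value, numeric(1))
    data.frame(endpoint = endpoint,
               calcifediol = sprintf("%d/%d (%.1f%%)", counts[1], ns[1],
                                     100 * counts[1] / ns[1]),
               calcitriol = sprintf("%d/%d (%.1f%%)", counts[2], ns[2],
                                    100 * counts[2] / ns[2]),
               placebo = sprintf("%d/%d (%.1f%%)", counts[3], ns[3],
                                 100 * counts[3] / ns[3]),
               p_calcifediol = pvals[1], p_calcitriol = pvals[2],
               test = "fisher", stringsAsFactors = FALSE)
  }
  cont_row <- function(endpoint, vals) {
    pvals <- vapply(c("calcifediol", "calcitriol"), function(a) {
      va <- vals[arm_idx[[a]]]; vp <- vals[arm_idx[["placebo"]]]
      rank_sum_test(va[!is.na(va)], vp[!is.na(vp)])$p.value
    }, numeric(1))
    data.frame(endpoint = endpoint,
               calcifediol = summ_med_iqr(vals[arm_idx$calcifediol]),
               calcitriol = summ_med_iqr(vals[arm_idx$calcitriol]),
               placebo = summ_med_iqr(vals[arm_idx$placebo]),
               p_calcifediol = pvals[1], p_calcitriol = pvals[2],
               test = "rank_sum", stringsAsFactors = FALSE)
  }
  rbind(
    binary_row("death_7d", died7),
    binary_row("krt_7d", krt7),
    binary_row("new_or_progressive_aki", npa),
    binary_row("krt_or_death_7d", composite),
    cont_row("peak_scr_7d", peak),
    cont_row("icu_free_days_28", icu_free),
    cont_row("hospital_free_days_28", hosp_free),
    binary_row("mortality_28d", died28),
    binary_row("hypercalcemia", hyperca),
    binary_row("hyperphosphatemia", hyperpo4))
}

#' CONSORT-style counts from a screening log
#'
#' Tallies a screening log into the counts a trial flow diagram reports:
#' patients screened, eligible (screen decision `include`), randomized per
#' arm, and per-reason exclusion counts.
#'
#' @param log Data frame with columns `decision` (`include` / `exclude` /
#'   `unscreenable`), `reasons` (`;`-separated codes, empty for includes),
#'   and optionally `arm` for randomized patients.
#' @return List with `screened`, `eligible`, `unscreenable`,
#'   `randomized` (named per-arm counts, if `arm` present), and
#'   `exclusion_reasons` (named counts).
#' @export
consort_counts <- function(log) {
  stopifnot(all(c("decision", "reasons") %in% names(log)))
  excl <- log$reasons[log$decision == "exclude"]
  reason_codes <- unlist(strsplit(excl[nzchar(excl)], ";", fixed = TRUE))
  randomized <- if ("arm" %in% names(log)) {
    assigned <- log$arm[log$decision == "include" & !is.na(log$arm)]
    vapply(ARMS, function(a) sum(assigned == a), numeric(1))
  } else NULL
  list(screened = nrow(log),
       eligible = sum(log$decision == "include"),
       unscreenable = sum(log$decision == "unscreenable"),
       randomized = randomized,
       exclusion_reasons = if (length(reason_codes))
         sort(table(reason_codes), decreasing = TRUE) else table(character(0)))
}

#' Run the full trial analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> KDIGO staging -> primary
#' global-rank comparisons -> secondary/safety outcome table -> subgroup
#' analyses, and optionally writes every artifact (CSV tables, a JSON
#' results file, and a reproducibility manifest) under `out_dir`. All
#' randomness flows from the single `seed` given to the generator, so a
#' rerun with the manifest's config and seed reproduces the outputs
#' byte-identically.
#'
#' @param config A [cohort_config()]; ignored when `cohort` is supplied.
#' @param seed Integer root seed.
#' @param cohort Optional pre-built or ingested `aki_cohort` (see
#'   [read_cohort()]); validated before analysis.
#' @param out_dir Optional output directory.
#' @param horizon_days Endpoint horizon.
#' @return List of class `akirank_results`: `cohort`, `stages`, `inputs`
#'   (with global ranks), `primary` (per-contrast statistics), `outcomes`,
#'   `subgroups`, `consort`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1, cohort = NULL,
                         out_dir = NULL, horizon_days = 7) {
  ingested <- !is.null(cohort)
  if (!ingested) cohort <- generate_cohort(config, seed)
  validate_cohort(cohort)

  stages <- stage_trajectory(cohort, horizon_days)
  inputs <- global_rank_inputs(cohort, horizon_days)
  ranked <- assign_global_ranks(inputs)

  primary <- lapply(c(calcifediol = "calcifediol", calcitriol = "calcitriol"),
                    function(a) {
    ct <- compare_arms(inputs[inputs$arm == a, ],
                       inputs[inputs$arm == "placebo", ])
    list(contrast = paste0(a, "_vs_placebo"), statistic = ct$statistic,
         p_value = ct$p.value, method = ct$method, n_active = ct$n1,
         n_placebo = ct$n2)
  })
  outcomes <- outcome_table(cohort, stages, horizon_days)
  subgroups <- subgroup_analysis(cohort, inputs, horizon_days)

  cfg_string <- paste(deparse(cohort$config %||% config), collapse = "")
  manifest <- list(
    package = "akirank",
    version = as.character(utils::packageVersion("akirank")),
    seed = if (ingested) NA else seed,
    ingested = ingested,
    config_hash = config_fingerprint(cfg_string),
    n_patients = nrow(cohort$patients),
    outputs = character(0))

  res <- list(cohort = cohort, stages = stages, inputs = ranked,
              primary = primary, outcomes = outcomes, subgroups = subgroups,
              consort = list(randomized = table(cohort$patients$arm)),
              manifest = manifest)
  class(res) <- "akirank_results"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, out_dir)
    files <- c(
      stages = file.path(out_dir, "stages.csv"),
      ranks = file.path(out_dir, "ranks.csv"),
      outcomes = file.path(out_dir, "outcomes.csv"),
      subgroups = file.path(out_dir, "subgroups.csv"))
    utils::write.csv(stages, files["stages"], row.names = FALSE)
    utils::write.csv(ranked, files["ranks"], row.names = FALSE)
    utils::write.csv(outcomes, files["outcomes"], row.names = FALSE)
    utils::write.csv(subgroups, files["subgroups"], row.names = FALSE)
    results_json <- file.path(out_dir, "results.json")
    jsonlite::write_json(list(primary = unname(primary)),
                         results_json, auto_unbox = TRUE, digits = NA)
    manifest$outputs <- c(file.path(out_dir, c("patients.csv", "labs.csv")),
                          unname(files), results_json)
    res$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.akirank_results <- function(x, ...) {
  cat("Hierarchical global-rank trial analysis\n")
  cat(sprintf("  %d patients", nrow(x$cohort$patients)))
  cat(sprintf(" (%s)\n", paste(sprintf("%s %d", names(x$consort$randomized),
                                       x$consort$randomized), collapse = ", ")))
  for (pr in x$primary)
    cat(sprintf("  %s: W = %g, p = %.3f (%s)\n", pr$contrast, pr$statistic,
                pr$p_value, pr$method))
  invisible(x)
}
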