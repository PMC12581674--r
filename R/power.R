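#' Analytic power for a two-sample standardized effect
#'
#' Normal-approximation power of a two-sided two-sample comparison of means
#' at a standardized effect `delta_sd` (in SD units):
#' `power = Phi(delta * sqrt(n/2) - z_{1 - alpha/2}) +
#'          Phi(-delta * sqrt(n/2) - z_{1 - alpha/2})`
#' (the second term is the vanishing opposite tail; keeping it makes the
#' power exactly `alpha` at `delta = 0`). With
#' `method = "t"` a noncentral-t refinement is used instead:
#' `power = P(|T| > t_crit)` with `df = 2n - 2` and noncentrality
#' `delta * sqrt(n/2)`.
#'
#' @param n_per_group Patients per group (>= 2).
#' @param delta_sd Standardized mean difference (SD units, >= 0).
#' @param alpha Two-sided significance level.
#' @param method `"normal"` (default) or `"t"`.
#' @return Power as a probability.
#' @export
#' @examples
#' analytic_power(50, 0.62, 0.025)  # ~0.805, reported as 80%
analytic_power <- function(n_per_group, delta_sd, alpha = 0.025,
                           method = c("normal", "t")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  if (delta_sd < 0) stop_config("delta_sd must be >= 0")
  if (any(n_per_group < 2)) stop_config("n_per_group must be >= 2")
  ncp <- delta_sd * sqrt(n_per_group / 2)
  if (method == "normal") {
    z <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
  } else {
    df <- 2 * n_per_group - 2
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  }
}

#' Smallest per-group sample size reaching a power target
#'
#' Inverts [analytic_power()]: starts from the closed-form
#' `n = 2 ((z_{1-alpha/2} + z_{power}) / delta)^2` and steps to the smallest
#' integer `n` whose analytic power meets the target.
#'
#' @param delta_sd Standardized effect (> 0).
#' @param power_target Target power in (0, 1).
#' @inheritParams analytic_power
#' @return Integer patients per group.
#' @export
#' @examples
#' required_n(0.62, 0.80, 0.025)  # 50
required_n <- function(delta_sd, power_target = 0.8, alpha = 0.025,
                       method = c("normal", "t")) {
  method <- match.arg(method)
  if (power_target <= 0 || power_target >= 1)
    stop_config("power_target must be in (0, 1)")
  if (delta_sd <= 0) stop_config("delta_sd must be > 0")
  n0 <- 2 * ((stats::qnorm(1 - alpha / 2) + stats::qnorm(power_target)) /
               delta_sd)^2
  n <- max(2, floor(n0) - 2)
  while (analytic_power(n, delta_sd, alpha, method) < power_target)
    n <- n + 1
  as.integer(n)
}

# Null generator for the global-rank endpoint: one common set of event
# risks and a standard-normal SCr-change distribution; delta shifts the
# active arm's mean change (a worse kidney course), and the optional event
# shifts add to the active arm's death/KRT risks.
simulate_rank_inputs <- function(n, p_death, p_krt, change_mean = 0,
                                 change_sd = 1) {
  died <- stats::runif(n) < p_death
  krt <- !died & stats::runif(n) < p_krt
  tier <- ifelse(died, "death", ifelse(krt, "krt", "scr"))
  change <- ifelse(tier == "scr", stats::rnorm(n, change_mean, change_sd),
                   NA_real_)
  data.frame(patient_id = seq_len(n), tier = tier, scr_mean_change = change,
             stringsAsFactors = FALSE)
}

#' Simulated power for t, Wilcoxon, or global-rank analyses
#'
#' Monte-Carlo power at a planted standardized effect. For `"t"` and
#' `"wilcoxon"`, two normal samples shifted by `delta_sd` SDs are compared
#' (Student's t, or the in-package rank-sum test). For `"global_rank"`, the
#' generator plants the shift in the SCr mean-change distribution of the
#' active arm on top of common death/KRT risks (optionally shifted by
#' `death_shift`/`krt_shift`), and arms are compared with [compare_arms()].
#'
#' @param n_per_group Patients per group.
#' @param delta_sd Standardized effect planted in the active group.
#' @param alpha Two-sided significance level.
#' @param test `"t"`, `"wilcoxon"`, or `"global_rank"`.
#' @param reps Monte-Carlo replicates (>= 100).
#' @param seed Optional seed.
#' @param p_death,p_krt Event risks shared by both arms under the null.
#' @param death_shift,krt_shift Additive risk shifts for the active arm.
#' @return List with `power`, `se` (binomial Monte-Carlo SE), `ci`
#'   (95% interval), `reps`, `test`.
#' @export
simulate_power <- function(n_per_group, delta_sd, alpha = 0.025,
                           test = c("t", "wilcoxon", "global_rank"),
                           reps = 1000, seed = NULL,
                           p_death = 0.122, p_krt = 0.082,
                           death_shift = 0, krt_shift = 0) {
  test <- match.arg(test)
  if (reps < 100) stop_config("reps must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  n <- n_per_group
  reject <- logical(reps)
  if (test == "t") {
    # vectorized across replicates: columns are replicates
    x <- matrix(stats::rnorm(n * reps, delta_sd), n, reps)
    y <- matrix(stats::rnorm(n * reps), n, reps)
    mx <- colMeans(x); my <- colMeans(y)
    vx <- colSums((x - rep(mx, each = n))^2) / (n - 1)
    vy <- colSums((y - rep(my, each = n))^2) / (n - 1)
    tstat <- (mx - my) / sqrt((vx + vy) / n)
    reject <- 2 * stats::pt(-abs(tstat), 2 * n - 2) < alpha
  } else if (test == "wilcoxon") {
    for (i in seq_len(reps)) {
      p <- rank_sum_test(stats::rnorm(n, delta_sd), stats::rnorm(n))$p.value
      reject[i] <- p < alpha
    }
  } else {
    for (i in seq_len(reps)) {
      a <- simulate_rank_inputs(n, p_death + death_shift, p_krt + krt_shift,
                                change_mean = delta_sd)
      b <- simulate_rank_inputs(n, p_death, p_krt)
      reject[i] <- compare_arms(a, b)$p.value < alpha
    }
  }
  est <- mean(reject)
  se <- sqrt(est * (1 - est) / reps)
  list(power = est, se = se,
       ci = c(max(0, est - 1.96 * se), min(1, est + 1.96 * se)),
       reps = reps, test = test)
}
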