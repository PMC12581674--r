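test_that("free days floor at zero and treat death as a competing risk", {
  expect_equal(free_days(5, NA), 23)
  expect_equal(free_days(5, 10), 0)    # died before day 28
  expect_equal(free_days(30, NA), 0)   # floor
  expect_equal(free_days(28, NA), 0)
  expect_equal(free_days(0, NA), 28)
  # death on day 28 itself is not "before day 28"
  expect_equal(free_days(5, 28), 23)
  # monotone nonincreasing in stay, always within [0, 28]
  fd <- free_days(0:40, NA)
  expect_true(all(diff(fd) <= 0))
  expect_true(all(fd >= 0 & fd <= 28))
  expect_error(free_days(-1, NA), "nonnegative")
})

test_that("new or progressive AKI compares the 7-day maximum to enrollment", {
  expect_true(new_or_progressive_aki(c(0, 0, 1, 0, 0, 0, 0), 0))
  expect_false(new_or_progressive_aki(rep(1, 7), 1))
  expect_true(new_or_progressive_aki(c(1, 1, 3, 3, 3, 3, 3), 1))  # KRT = stage 3
  st <- data.frame(day = 0:7, stage = c(1, rep(1, 6), 2))
  expect_true(new_or_progressive_aki(st, 1))
})

test_that("krt_or_death and peak creatinine follow the 7-day window", {
  expect_true(krt_or_death(6, NA))
  expect_false(krt_or_death(NA, NA))
  expect_true(krt_or_death(NA, 3))
  expect_false(krt_or_death(10, NA))   # death after the window
  s <- lab_series("scr", "mg/dL", c(0, 24, 48), c(1.1, 2.4, 1.8))
  expect_equal(peak_scr(s), 2.4)
  s <- lab_series("scr", "mg/dL", c(0, 200), c(1.1, 9.9))
  expect_equal(peak_scr(s, 7), 1.1)    # day-8 value outside window
})

test_that("safety thresholds are strict and peaks are located", {
  ca <- lab_series("calcium", "mg/dL", 24 * (0:7), c(rep(9, 7), 11.6))
  po4 <- lab_series("phosphate", "mg/dL", 24 * (0:7), rep(4, 8))
  fl <- safety_flags(ca, po4)
  expect_true(fl$hypercalcemia)
  expect_equal(fl$ca_peak, 11.6)
  expect_equal(fl$ca_peak_day, 7)
  expect_false(fl$hyperphosphatemia)

  # boundary values do not flag
  ca_b <- lab_series("calcium", "mg/dL", c(0, 24), c(10.7, 10.7))
  po4_b <- lab_series("phosphate", "mg/dL", c(0, 24), c(6.0, 6.0))
  fl <- safety_flags(ca_b, po4_b)
  expect_false(fl$hypercalcemia)
  expect_false(fl$hyperphosphatemia)
})

test_that("Fisher p-values match the hypergeometric point-probability oracle", {
  expect_equal(compare_binary(2, 4, 2, 4)$p.value, 1)
  expect_equal(compare_binary(0, 5, 5, 5)$p.value, 2 / 252, tolerance = 1e-12)
  # the trial's KRT counts: 1/51 vs 4/49
  expect_equal(compare_binary(1, 51, 4, 49)$p.value,
               fisher_enum_p(1, 50, 4, 45), tolerance = 1e-12)
  set.seed(201)
  for (i in 1:50) {
    an <- sample(1:15, 1); bn <- sample(1:15, 1)
    a <- sample(0:an, 1); b <- sample(0:bn, 1)
    expect_equal(compare_binary(a, an, b, bn)$p.value,
                 fisher_enum_p(a, an - a, b, bn - b), tolerance = 1e-10,
                 info = sprintf("%d/%d vs %d/%d", a, an, b, bn))
  }
  # chi-squared route, no continuity correction by default
  p_chi <- compare_binary(10, 50, 20, 50, method = "chi2")$p.value
  expect_equal(p_chi,
               suppressWarnings(stats::chisq.test(
                 matrix(c(10, 40, 20, 30), 2, byrow = TRUE),
                 correct = FALSE)$p.value))
  expect_error(compare_binary(1, 0, 1, 5), "positive")
  expect_error(compare_binary(6, 5, 1, 5), "\\[0, n\\]")
})

test_that("KIM-1 normalization is scale-invariant and guards zero creatinine", {
  expect_equal(normalize_kim1(1000, 100), 10)
  expect_equal(normalize_kim1(2000, 200), normalize_kim1(1000, 100))
  expect_error(normalize_kim1(1000, 0), "positive")
})

test_that("vitamin D status thresholds classify nested categories", {
  x <- c(5, 9.9, 10, 15, 19.9, 20, 25, 29.9, 30, 40)
  s <- vitd_status_summary(x)
  expect_equal(s$count[s$category == "insufficient"], 8)        # < 30
  expect_equal(s$count[s$category == "deficient"], 5)           # < 20
  expect_equal(s$count[s$category == "severely_deficient"], 2)  # < 10
  expect_equal(s$n, rep(10, 3))
  expect_equal(s$pct, c(80, 50, 20))
  # missing values drop from the denominator
  s2 <- vitd_status_summary(c(x, NA, NA))
  expect_equal(s2$n, rep(10, 3))
})

test_that("SOFA sums six configurable organ subscores", {
  normal <- list(respiration = 450, coagulation = 200, liver = 0.8,
                 cardiovascular = 0, cns = 15, renal = 0.9)
  expect_equal(sofa_daily(normal)$total, 0)

  worst <- list(respiration = 80, coagulation = 10, liver = 15,
                cardiovascular = 4, cns = 3, renal = 6)
  expect_equal(sofa_daily(worst)$total, 24)

  one_organ <- normal
  one_organ$renal <- 6
  expect_equal(sofa_daily(one_organ)$total, 4)

  # missing organ scores 0 and is flagged; carry-forward is available
  miss <- normal
  miss$cns <- NULL
  out <- sofa_daily(miss)
  expect_equal(out$total, 0)
  expect_equal(out$missing_organs, "cns")
  prev <- stats::setNames(c(0L, 0L, 0L, 0L, 3L, 0L), names(sofa_score_table()))
  out <- sofa_daily(miss, missing = "carry", previous = prev)
  expect_equal(out$total, 3)

  # YAML grid is equivalent to the built-in one
  expect_equal(sofa_daily(worst, sofa_table_from_yaml())$total, 24)
})

test_that("mixed-model comparison detects planted offsets and degenerate designs", {
  mk_long <- function(n_per_arm, offset, sd) {
    g <- rep(c("active", "placebo"), each = n_per_arm * 4)
    id <- rep(seq_len(2 * n_per_arm), each = 4)
    day <- rep(0:3, 2 * n_per_arm)
    mu <- ifelse(g == "active", 10 + offset, 10)
    data.frame(patient_id = id, group = g, time = day,
               value = stats::rnorm(length(g), mu, sd))
  }
  set.seed(301)
  big <- longitudinal_compare(mk_long(50, 5, 0.1))
  expect_true(big$estimable)
  expect_lt(big$p_group, 0.001)

  null <- longitudinal_compare(mk_long(50, 0, 1e-6))
  expect_gt(null$p_group, 0.5)

  # one group only: not estimable, no exception
  d <- mk_long(5, 0, 1)
  d$group <- "active"
  out <- longitudinal_compare(d)
  expect_false(out$estimable)
  expect_true(is.na(out$p_group))
})

test_that("null rejection of the mixed-model group test is near nominal", {
  set.seed(302)
  rej <- 0
  reps <- 60
  for (i in seq_len(reps)) {
    id <- rep(1:30, each = 3)
    d <- data.frame(patient_id = id,
                    group = rep(rep(c("a", "b"), each = 15), each = 3),
                    time = rep(0:2, 30),
                    value = stats::rnorm(90, 10, 2) +
                      rep(stats::rnorm(30, 0, 1), each = 3))
    p <- longitudinal_compare(d)$p_group
    if (!is.na(p) && p < 0.05) rej <- rej + 1
  }
  # loose binomial bound around 5% at 60 replicates
  expect_lte(rej, stats::qbinom(0.999, reps, 0.05) + 2)
})

test_that("Rubin pooling is the identity without missingness and degrades gracefully", {
  set.seed(303)
  d <- data.frame(x = stats::rnorm(40))
  d$y <- 2 + 1.5 * d$x + stats::rnorm(40, 0, 0.5)

  pooled <- mice_pool(d, y ~ x, m = 5, seed = 1)
  ref <- summary(stats::lm(y ~ x, d))$coefficients
  expect_equal(pooled$estimate, unname(ref[, "Estimate"]), tolerance = 1e-12)
  expect_equal(pooled$se, unname(ref[, "Std. Error"]), tolerance = 1e-12)

  # m = 1: pooled SE equals the single-imputation SE
  d_miss <- d
  d_miss$y[sample(40, 8)] <- NA
  p1 <- mice_pool(d_miss, y ~ x, m = 1, seed = 2)
  expect_true(all(is.finite(p1$se)))
  expect_equal(nrow(p1), 2)

  # all-missing column errors
  d_bad <- d
  d_bad$x <- NA_real_
  expect_error(mice_pool(d_bad, y ~ x), "entirely missing")
})

test_that("pooled estimates recover the generating slope under MCAR missingness", {
  set.seed(304)
  hits <- 0
  reps <- 25
  for (i in seq_len(reps)) {
    x <- stats::rnorm(60)
    z <- 0.5 * x + stats::rnorm(60)           # auxiliary, helps imputation
    y <- 1 + 2 * x + stats::rnorm(60, 0, 1)
    d <- data.frame(x = x, z = z, y = y)
    d$y[stats::runif(60) < 0.2] <- NA         # 20% MCAR
    pooled <- mice_pool(d, y ~ x, m = 5)
    slope <- pooled[pooled$term == "x", ]
    ci <- slope$estimate + c(-1, 1) * stats::qt(0.975, slope$df) * slope$se
    if (ci[1] <= 2 && 2 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9 - 3 * sqrt(0.9 * 0.1 / reps))
})
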