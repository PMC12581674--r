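test_that("baseline-adjusted mean change averages daily percent deviations", {
  s <- lab_series("scr", "mg/dL", c(0, 24, 48), c(1.0, 1.2, 1.4))
  expect_equal(baseline_adjusted_mean_change(s, 1.0), 30)

  s <- lab_series("scr", "mg/dL", c(0, 24, 48, 72), rep(1.3, 4))
  expect_equal(baseline_adjusted_mean_change(s, 1.3), 0)

  s <- lab_series("scr", "mg/dL", c(0, 96), c(2.0, 1.0))
  expect_equal(baseline_adjusted_mean_change(s, 2.0), -50)

  # observations at/after KRT start are excluded
  s <- lab_series("scr", "mg/dL", c(0, 24, 48, 72), c(1, 1.1, 2.0, 3.0))
  expect_equal(baseline_adjusted_mean_change(s, 1, krt_start_day = 2), 10)

  # day-0 value is never averaged; no eligible obs -> unevaluable NA
  s <- lab_series("scr", "mg/dL", 0, 1.0)
  out <- baseline_adjusted_mean_change(s, 1.0)
  expect_true(is.na(out))
  expect_true(attr(out, "unevaluable"))

  expect_error(baseline_adjusted_mean_change(s, 0), "positive")
})

test_that("global ranks order death > KRT > ascending creatinine change", {
  x <- mk_inputs(c("death", "krt", "scr", "scr", "scr"),
                 c(NA, NA, 40, 0, -20), ids = LETTERS[1:5])
  r <- assign_global_ranks(x)
  expect_equal(r$rank, c(5, 4, 3, 2, 1))

  # two deaths among 5 share midrank 4.5
  x <- mk_inputs(c("death", "death", "scr", "scr", "scr"),
                 c(NA, NA, 10, 0, -10))
  expect_equal(sort(assign_global_ranks(x)$rank),
               c(1, 2, 3, 4.5, 4.5))

  # full tie: everyone at (n+1)/2
  x <- mk_inputs(rep("scr", 4), rep(7, 4))
  expect_equal(assign_global_ranks(x)$rank, rep(2.5, 4))

  expect_error(assign_global_ranks(mk_inputs(c("scr", "scr"), c(1, 2),
                                             ids = c("a", "a"))),
               "duplicate")
})

test_that("midranks always sum to n(n+1)/2 over random tiered cohorts", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(2:40, 1)
    tier <- sample(c("death", "krt", "scr"), n, replace = TRUE,
                   prob = c(0.2, 0.1, 0.7))
    change <- ifelse(tier == "scr",
                     round(stats::rnorm(n, 0, 25), sample(0:1, 1)), NA)
    r <- assign_global_ranks(mk_inputs(tier, change))
    expect_equal(sum(r$rank), n * (n + 1) / 2)
  }
})

test_that("worsening a patient's tier never improves their rank", {
  set.seed(102)
  for (i in 1:40) {
    n <- sample(4:25, 1)
    tier <- sample(c("death", "krt", "scr"), n, replace = TRUE,
                   prob = c(0.2, 0.1, 0.7))
    change <- ifelse(tier == "scr", stats::rnorm(n, 0, 25), NA)
    base <- assign_global_ranks(mk_inputs(tier, change))
    j <- sample(n, 1)
    worse <- tier
    worse[j] <- switch(tier[j], scr = "krt", krt = "death", death = "death")
    change2 <- change
    change2[j] <- NA
    after <- assign_global_ranks(mk_inputs(worse, change2))
    expect_gte(after$rank[j], base$rank[j])
  }
})

test_that("ranks and p-values are invariant to increasing transforms of the change", {
  set.seed(103)
  tier <- sample(c("death", "krt", "scr"), 30, replace = TRUE,
                 prob = c(0.15, 0.1, 0.75))
  change <- ifelse(tier == "scr", stats::rnorm(30, 0, 20), NA)
  arm <- rep(c("a", "b"), 15)
  mono <- function(x) sign(x) * log1p(abs(x)) * 3 + 2  # strictly increasing
  x1 <- mk_inputs(tier, change)
  x2 <- mk_inputs(tier, ifelse(is.na(change), NA, mono(change)))
  expect_equal(assign_global_ranks(x1)$rank, assign_global_ranks(x2)$rank)
  p1 <- compare_arms(x1[arm == "a", ], x1[arm == "b", ])
  p2 <- compare_arms(x2[arm == "a", ], x2[arm == "b", ])
  expect_equal(p1$p.value, p2$p.value)
  expect_equal(p1$statistic, p2$statistic)
})

test_that("exact rank-sum p-values match enumeration and its conventions", {
  # {1,2} vs {3,4}: doubled lower tail = 1/3
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$p.value, 1 / 3)
  # identical outcome multisets: p = 1
  x <- mk_inputs(c("death", "scr", "scr"), c(NA, 5, -5))
  expect_equal(compare_arms(x, x)$p.value, 1)
  # random tied instances vs the independent enumeration oracle
  set.seed(104)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    keys <- sample(1:5, n1 + n2, replace = TRUE) + stats::runif(n1 + n2) *
      (stats::runif(1) < 0.5)
    got <- rank_sum_test(keys[1:n1], keys[n1 + 1:n2])
    expect_equal(got$method, "exact")
    expect_equal(got$p.value, enum_rank_sum_p(keys[1:n1], keys[n1 + 1:n2]))
  }
  expect_error(rank_sum_test(numeric(0), 1:3), "nonempty")
})

test_that("the approximate path agrees with wilcox.test on untied data", {
  set.seed(105)
  for (i in 1:20) {
    n1 <- sample(10:30, 1); n2 <- sample(10:30, 1)
    x <- stats::rnorm(n1); y <- stats::rnorm(n2, 0.3)
    ours <- rank_sum_test(x, y, exact_limit = 0, refine = FALSE)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("arm comparisons recompute pooled ranks and reject empty arms", {
  set.seed(106)
  tier <- sample(c("death", "krt", "scr"), 60, replace = TRUE,
                 prob = c(0.12, 0.06, 0.82))
  change <- ifelse(tier == "scr", stats::rnorm(60, 0, 20), NA)
  x <- mk_inputs(tier, change)
  arm3 <- rep(c("a", "b", "c"), each = 20)
  # two-arm comparison must not depend on the third arm's presence
  p_ab <- compare_arms(x[arm3 == "a", ], x[arm3 == "b", ])
  p_ab2 <- compare_arms(x[arm3 == "a", ][sample(20), ], x[arm3 == "b", ])
  expect_equal(p_ab$p.value, p_ab2$p.value)
  expect_error(compare_arms(x[0, ], x), "nonempty")
})

test_that("subgroup analyses recover a planted subgroup-confined harm", {
  cfg <- cohort_config(n_per_arm = 60)
  co <- suppressWarnings(generate_cohort(cfg, seed = 55))
  inputs <- suppressWarnings(global_rank_inputs(co))
  # plant a large creatinine rise for calcitriol patients in medical ICUs
  med <- co$patients$icu_type[match(inputs$patient_id,
                                    co$patients$patient_id)] == "medical"
  hit <- inputs$arm == "calcitriol" & med & inputs$tier == "scr"
  inputs$scr_mean_change[hit] <- inputs$scr_mean_change[hit] + 80

  sg <- subgroup_analysis(co, inputs)
  expect_true(all(c("subgroup", "level", "contrast", "p_value") %in% names(sg)))
  p_med <- sg$p_value[sg$subgroup == "icu_type" & sg$level == "medical" &
                        sg$contrast == "calcitriol_vs_placebo"]
  pooled <- compare_arms(inputs[inputs$arm == "calcitriol", ],
                         inputs[inputs$arm == "placebo", ])$p.value
  expect_lt(p_med, pooled)

  # a subgroup level spanning the whole cohort reproduces the primary result
  co_all_med <- co
  co_all_med$patients$icu_type <- "medical"
  sg_all <- subgroup_analysis(co_all_med, inputs)
  p_whole <- sg_all$p_value[sg_all$subgroup == "icu_type" &
                              sg_all$contrast == "calcitriol_vs_placebo"]
  expect_equal(p_whole, compare_arms(inputs[inputs$arm == "calcitriol", ],
                                     inputs[inputs$arm == "placebo", ])$p.value)

  # an empty cell is reported as not estimable, not an error
  co2 <- co
  keep <- co2$patients$arm != "placebo" | co2$patients$icu_type != "surgical"
  co2$patients <- co2$patients[keep, ]
  co2$labs <- co2$labs[co2$labs$patient_id %in% co2$patients$patient_id, ]
  inputs2 <- inputs[inputs$patient_id %in% co2$patients$patient_id, ]
  sg2 <- subgroup_analysis(co2, inputs2)
  surg <- sg2[sg2$subgroup == "icu_type" & sg2$level == "surgical", ]
  expect_true(all(surg$method == "not_estimable"))
  expect_true(all(is.na(surg$p_value)))
})

test_that("survivors without post-baseline creatinine are flagged, not dropped", {
  cfg <- cohort_config(n_per_arm = 2,
                       death_risk_7d = c(calcifediol = 0, calcitriol = 0,
                                         placebo = 0),
                       krt_risk_7d = c(calcifediol = 0, calcitriol = 0,
                                       placebo = 0),
                       death_risk_28d = c(calcifediol = 0, calcitriol = 0,
                                          placebo = 0))
  co <- generate_cohort(cfg, seed = 2)
  # strip one patient's post-baseline SCr
  pid <- co$patients$patient_id[1]
  drop <- co$labs$patient_id == pid & co$labs$analyte == "scr" &
    co$labs$time_h > 0
  co$labs <- co$labs[!drop, ]
  expect_warning(inp <- global_rank_inputs(co), "no post-baseline")
  row <- inp[inp$patient_id == pid, ]
  expect_true(row$unevaluable)
  expect_equal(row$scr_mean_change, 0)
  expect_equal(nrow(inp), 6)
})
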