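# Shared fixtures and independent oracles used across the test files.

# Quick endpoint-input table for rank tests.
mk_inputs <- function(tier, change = NULL, ids = NULL) {
  n <- length(tier)
  data.frame(
    patient_id = ids %||% paste0("p", seq_len(n)),
    tier = tier,
    scr_mean_change = if (is.null(change)) ifelse(tier == "scr", 0, NA)
    else change,
    stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact two-sided rank-sum p by full enumeration of group assignments;
# independent of the package's enumeration (works from raw severity keys).
enum_rank_sum_p <- function(keys_a, keys_b) {
  n1 <- length(keys_a)
  r <- rank(c(keys_a, keys_b))
  N <- length(r)
  cmb <- utils::combn(N, n1)
  Ws <- colSums(matrix(r[cmb], nrow = n1))
  w <- sum(r[seq_len(n1)])
  min(1, 2 * min(mean(Ws <= w + 1e-9), mean(Ws >= w - 1e-9)))
}

# Fisher two-sided p by explicit hypergeometric point-probability
# enumeration over the table's support.
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Brute-force KDIGO creatinine staging: scan every candidate reference
# observation in each lookback window against the value current at t.
brute_stage_scr <- function(scr, at_time) {
  obs <- scr[scr$time_h <= at_time, , drop = FALSE]
  if (nrow(obs) == 0) return(0L)
  current <- obs$value[which.max(obs$time_h)]
  stage <- 0L
  for (i in seq_len(nrow(obs))) {
    dt <- at_time - obs$time_h[i]
    if (dt <= 48 && current - obs$value[i] >= 0.3) stage <- max(stage, 1L)
    if (dt <= 24 * 7) {
      rel <- current / obs$value[i] - 1
      if (rel >= 1.0) stage <- max(stage, 2L)
      else if (rel >= 0.5) stage <- max(stage, 1L)
    }
  }
  stage
}

# Random SCr series on a small grid, used by staging property tests.
random_scr_series <- function(n_obs) {
  t <- sort(sample(0:240, n_obs))
  lab_series("scr", "mg/dL", t, round(stats::runif(n_obs, 0.4, 3.5), 2))
}
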