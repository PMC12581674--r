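#' Mixed-model comparison of longitudinal lab trajectories
#'
#' Repeated-measures linear mixed model for a longitudinal parameter
#' (e.g. 25D, calcium, SOFA): fixed effects for group, time, and their
#' interaction; a random intercept per patient. Returns the group
#' main-effect p-value. Model fitting is delegated to [nlme::lme()]; the
#' contract here is the model specification and the returned contrast. A
#' singular or otherwise unfittable design yields a not-estimable marker
#' instead of an error.
#'
#' @param data Data frame with columns `patient_id`, `group`, `time`,
#'   `value` (other names via the arguments below).
#' @param value,group,time,id Column names.
#' @return List with `p_group` (`NA` when not estimable), `estimable`,
#'   and `model` (the fitted `lme`, or `NULL`).
#' @export
longitudinal_compare <- function(data, value = "value", group = "group",
                                 time = "time", id = "patient_id") {
  d <- data.frame(value = data[[value]], group = factor(data[[group]]),
                  time = data[[time]], id = data[[id]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$group)) < 2)
    return(list(p_group = NA_real_, estimable = FALSE, model = NULL))
  fit <- tryCatch(
    nlme::lme(value ~ group * time, random = ~ 1 | id, data = d,
              na.action = stats::na.omit),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(p_group = NA_real_, estimable = FALSE, model = NULL))
  an <- tryCatch(stats::anova(fit), error = function(e) NULL)
  if (is.null(an) || !"group" %in% rownames(an))
    return(list(p_group = NA_real_, estimable = FALSE, model = fit))
  list(p_group = an["group", "p-value"], estimable = TRUE, model = fit)
}

# One sweep of chained-equation imputation: each incomplete numeric column
# is regressed on all other columns over its observed rows; coefficients
# are drawn from the approximate posterior and missing entries filled with
# prediction + residual noise (stochastic regression imputation).
impute_chained_once <- function(data, miss_idx, maxit = 5) {
  d <- data
  # initialize missing cells with column means
  for (j in names(miss_idx))
    d[[j]][miss_idx[[j]]] <- mean(data[[j]], na.rm = TRUE)
  for (it in seq_len(maxit)) {
    for (j in names(miss_idx)) {
      mis <- miss_idx[[j]]
      others <- setdiff(names(d), j)
      X <- cbind(1, as.matrix(d[others]))
      y_obs <- data[[j]][!mis]
      X_obs <- X[!mis, , drop = FALSE]
      fit <- tryCatch(stats::lm.fit(X_obs, y_obs), error = function(e) NULL)
      if (is.null(fit)) next
      keep <- !is.na(fit$coefficients)
      beta <- fit$coefficients[keep]
      Xk <- X_obs[, keep, drop = FALSE]
      dof <- max(1, length(y_obs) - sum(keep))
      sigma2 <- sum(fit$residuals^2) / stats::rchisq(1, dof)
      XtX_inv <- tryCatch(chol2inv(chol(crossprod(Xk))), error = function(e) NULL)
      if (!is.null(XtX_inv)) {
        beta <- beta + drop(chol(sigma2 * XtX_inv) %*% stats::rnorm(sum(keep)))
      }
      pred <- drop(X[mis, keep, drop = FALSE] %*% beta)
      d[[j]][mis] <- pred + stats::rnorm(sum(mis), 0, sqrt(sigma2))
    }
  }
  d
}

#' Multiple imputation with Rubin's-rules pooling
#'
#' Creates `m` completed datasets by chained-equation stochastic regression
#' imputation of the numeric columns, fits `lm(formula)` on each, and pools
#' the coefficients with Rubin's rules: pooled estimate = mean of the `m`
#' estimates; total variance = within-imputation variance plus
#' `(1 + 1/m)` times the between-imputation variance; inference on the
#' Rubin-derived t reference. With no missing data the procedure is the
#' identity: every imputation equals the observed data, the between
#' variance is zero, and the pooled fit coincides exactly with the
#' complete-data fit.
#'
#' @param data Data frame of numeric columns, possibly with `NA`s.
#' @param formula Analysis model passed to [stats::lm()].
#' @param m Number of imputations (default 5).
#' @param seed Optional seed.
#' @param maxit Chained-equation sweeps per imputation.
#' @return Data frame with one row per coefficient: `term`, `estimate`,
#'   `se`, `df`, `p.value`, plus attributes `m` and `missing_fraction`.
#' @export
mice_pool <- function(data, formula, m = 5, seed = NULL, maxit = 5) {
  if (!is.null(seed)) set.seed(seed)
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  miss <- vapply(data[num_cols], function(x) mean(is.na(x)), numeric(1))
  if (any(miss == 1))
    stop_config("column(s) entirely missing: %s",
                paste(num_cols[miss == 1], collapse = ", "))
  non_num_na <- vapply(data[setdiff(names(data), num_cols)],
                       anyNA, logical(1))
  if (any(non_num_na))
    stop_config("non-numeric columns with missing values are not supported")
  miss_idx <- lapply(data[num_cols], is.na)
  miss_idx <- miss_idx[vapply(miss_idx, any, logical(1))]

  fits <- vector("list", m)
  for (k in seq_len(m)) {
    completed <- data
    if (length(miss_idx)) {
      imputed <- impute_chained_once(data[num_cols], miss_idx, maxit)
      completed[num_cols] <- imputed
    }
    fits[[k]] <- stats::lm(formula, data = completed)
  }
  est <- t(vapply(fits, stats::coef, stats::coef(fits[[1]])))
  ses <- t(vapply(fits, function(f) summary(f)$coefficients[, "Std. Error"],
                  stats::coef(fits[[1]])))
  qbar <- colMeans(est)
  ubar <- colMeans(ses^2)
  b <- if (m > 1) apply(est, 2, stats::var) else rep(0, length(qbar))
  total <- ubar + (1 + 1 / m) * b
  # Rubin's large-sample degrees of freedom; infinite when B = 0
  df <- ifelse(b > 0, (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2, Inf)
  p <- 2 * stats::pt(-abs(qbar / sqrt(total)), df)
  out <- data.frame(term = names(qbar), estimate = unname(qbar),
                    se = unname(sqrt(total)), df = unname(df),
                    p.value = unname(p), stringsAsFactors = FALSE)
  attr(out, "m") <- m
  attr(out, "missing_fraction") <- miss
  out
}
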