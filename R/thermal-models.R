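#' Label days as thermally optimal or sub-optimal
#'
#' A day is optimal when every high-frequency reading that day is at or below
#' the thermal optimum (default 24 degC for *Zostera muelleri*); otherwise it
#' is sub-optimal. Days whose readings are all missing are skipped with a
#' warning.
#'
#' @param hf Data.frame with columns `timestamp`, `temp_c` (30-minute logger
#'   series).
#' @param optimal_threshold Thermal optimum in degC (> 0).
#' @return Data.frame with columns `date` and logical `suboptimal`.
#' @export
label_daily_optimality <- function(hf, optimal_threshold = 24) {
  stopifnot(all(c("timestamp", "temp_c") %in% names(hf)),
            optimal_threshold > 0)
  day <- as.Date(hf$timestamp, tz = "UTC")
  ok <- !is.na(hf$temp_c)
  n_ok <- tapply(ok, day, sum)
  if (any(n_ok == 0)) {
    warning(sprintf("%d day(s) with no valid readings skipped", sum(n_ok == 0)),
            call. = FALSE)
  }
  keep <- names(n_ok)[n_ok > 0]
  mx <- tapply(hf$temp_c[ok], day[ok], max)
  data.frame(date = as.Date(keep),
             suboptimal = unname(mx[keep] > optimal_threshold))
}

#' Daily maxima and heat-stress classification from logger data
#'
#' Extracts each day's maximum reading and flags heat-stress days whose
#' maximum meets or exceeds the shoot-mortality threshold (default 30 degC).
#'
#' @inheritParams label_daily_optimality
#' @param mortality_threshold Shoot-mortality threshold in degC.
#' @return Data.frame `date`, `y_max`, logical `heat_stress`.
#' @export
daily_maxima <- function(hf, mortality_threshold = 30) {
  stopifnot(all(c("timestamp", "temp_c") %in% names(hf)))
  day <- as.Date(hf$timestamp, tz = "UTC")
  ok <- !is.na(hf$temp_c)
  mx <- tapply(hf$temp_c[ok], day[ok], max)
  data.frame(date = as.Date(names(mx)), y_max = unname(mx),
             heat_stress = unname(mx) >= mortality_threshold)
}

#' Fit the daily thermal-optimality model
#'
#' Maximum-likelihood logistic regression of the sub-optimal-day indicator on
#' daily mean SST: `logit P(sub-optimal) = beta0 + beta1 * SST_d`. McFadden's
#' pseudo-R-squared is reported as `1 - loglik_model / loglik_null` against the
#' intercept-only model.
#'
#' @param labels Output of [label_daily_optimality()].
#' @param daily_sst Data.frame with columns `date`, `sst_c` (daily mean SST;
#'   one member or an ensemble mean).
#' @param optimal_threshold Threshold recorded on the fitted object.
#' @return Object of class `thermal_optimality_model` with components
#'   `coefficients` (beta0, beta1), `loglik_model`, `loglik_null`,
#'   `mcfadden_r2`, `n`, and the underlying `glm` fit.
#' @export
fit_optimality_model <- function(labels, daily_sst, optimal_threshold = 24) {
  d <- merge(labels, daily_sst[, c("date", "sst_c")], by = "date")
  d <- d[stats::complete.cases(d[, c("suboptimal", "sst_c")]), ]
  if (nrow(d) < 30) {
    stop("need at least 30 matched days to fit the optimality model",
         call. = FALSE)
  }
  if (length(unique(d$suboptimal)) < 2) {
    stop("cannot fit: all days share one optimality class", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(suboptimal ~ sst_c, family = stats::binomial(), data = d)
  )
  fitted_p <- stats::fitted(fit)
  separated <- min(fitted_p[fit$y == 1]) > max(fitted_p[fit$y == 0]) &&
    fit$deviance < 1e-4
  if (separated) {
    stop("perfect separation: the two classes are linearly separable in SST",
         call. = FALSE)
  }
  if (!fit$converged) {
    stop("logistic fit did not converge", call. = FALSE)
  }
  ll_model <- as.numeric(stats::logLik(fit))
  null_fit <- stats::glm(suboptimal ~ 1, family = stats::binomial(), data = d)
  ll_null <- as.numeric(stats::logLik(null_fit))
  structure(list(
    coefficients = stats::setNames(stats::coef(fit), c("beta0", "beta1")),
    optimal_threshold = optimal_threshold,
    loglik_model = ll_model, loglik_null = ll_null,
    mcfadden_r2 = 1 - ll_model / ll_null,
    n = nrow(d), fit = fit
  ), class = "thermal_optimality_model")
}

#' @export
print.thermal_optimality_model <- function(x, ...) {
  cat("Thermal optimality model (logistic): ",
      sprintf("logit p = %.4f %+.4f * SST_d\n",
              x$coefficients[1], x$coefficients[2]))
  cat(sprintf("  n = %d days, threshold %.1f degC\n", x$n, x$optimal_threshold))
  cat(sprintf("  loglik %.3f (null %.3f), McFadden R2 = %.4f\n",
              x$loglik_model, x$loglik_null, x$mcfadden_r2))
  invisible(x)
}

#' @export
coef.thermal_optimality_model <- function(object, ...) object$coefficients

#' Predict the daily sub-optimality probability
#'
#' @param object A `thermal_optimality_model`.
#' @param sst Numeric vector of daily mean SST (degC), or a data.frame with an
#'   `sst_c` column.
#' @param ... Unused.
#' @return Vector of probabilities of a day being thermally sub-optimal.
#' @export
predict.thermal_optimality_model <- function(object, sst, ...) {
  if (is.data.frame(sst)) sst <- sst$sst_c
  stats::plogis(object$coefficients[1] + object$coefficients[2] * sst)
}

#' @export
summary.thermal_optimality_model <- function(object, ...) {
  s <- summary(object$fit)
  s$mcfadden_r2 <- object$mcfadden_r2
  s
}

#' Fit the daily-maximum temperature model
#'
#' Least-squares regression of the daily maximum temperature on daily mean SST
#' with a seasonal month term: `Y_d = beta0 + beta1 * SST_d + month effect`.
#' The month enters as a factor by default (reference month fixed to the first
#' month present, effect 0); a numeric-month encoding is available for
#' comparison with the strict linear-in-month notation.
#'
#' @param maxima Output of [daily_maxima()].
#' @param daily_sst Data.frame `date`, `sst_c`.
#' @param month_encoding `"categorical"` (default) or `"numeric"`.
#' @return Object of class `max_temp_model` with `coefficients` (beta0, beta1),
#'   `month_effects` (length-12 additive offsets; NA for unobserved months
#'   under the categorical encoding), `r2`, `residual_sd`, `month_encoding`,
#'   and the underlying `lm` fit.
#' @export
fit_max_temp_model <- function(maxima, daily_sst,
                               month_encoding = c("categorical", "numeric")) {
  month_encoding <- match.arg(month_encoding)
  d <- merge(maxima[, c("date", "y_max")], daily_sst[, c("date", "sst_c")],
             by = "date")
  d <- d[stats::complete.cases(d), ]
  d$month <- date_month(d$date)
  if (nrow(d) < 60) {
    stop("need at least 60 matched days to fit the daily-maximum model",
         call. = FALSE)
  }
  months_present <- sort(unique(d$month))
  if (length(months_present) < 2) {
    stop("need data from at least 2 distinct months", call. = FALSE)
  }
  if (month_encoding == "categorical") {
    d$month_f <- factor(d$month, levels = months_present)
    fit <- stats::lm(y_max ~ sst_c + month_f, data = d)
    cf <- stats::coef(fit)
    eff <- rep(NA_real_, 12)
    eff[months_present[1]] <- 0
    for (m in months_present[-1]) {
      eff[m] <- unname(cf[paste0("month_f", m)])
    }
  } else {
    fit <- stats::lm(y_max ~ sst_c + month, data = d)
    cf <- stats::coef(fit)
    eff <- unname(cf["month"]) * (1:12)
  }
  s <- suppressWarnings(summary(fit))  # zero-residual fits warn harmlessly
  structure(list(
    coefficients = c(beta0 = unname(cf["(Intercept)"]),
                     beta1 = unname(cf["sst_c"])),
    month_effects = eff,
    r2 = s$r.squared, residual_sd = s$sigma,
    month_encoding = month_encoding,
    months_present = months_present,
    n = nrow(d), fit = fit
  ), class = "max_temp_model")
}

#' @export
print.max_temp_model <- function(x, ...) {
  cat(sprintf(
    "Daily-maximum model (OLS, %s month): Y_d = %.4f %+.4f * SST_d + month\n",
    x$month_encoding, x$coefficients[1], x$coefficients[2]))
  cat(sprintf("  n = %d days, R2 = %.4f, residual sd = %.3f degC\n",
              x$n, x$r2, x$residual_sd))
  invisible(x)
}

#' @export
coef.max_temp_model <- function(object, ...) {
  c(object$coefficients, stats::setNames(object$month_effects,
                                         paste0("month", 1:12)))
}

#' Predict the daily maximum temperature
#'
#' @param object A `max_temp_model`.
#' @param newdata Data.frame with columns `sst_c` and `month` (or `date`).
#' @param ... Unused.
#' @return Vector of predicted daily maxima (degC).
#' @export
predict.max_temp_model <- function(object, newdata, ...) {
  if (!"month" %in% names(newdata)) {
    newdata$month <- date_month(as.Date(newdata$date))
  }
  eff <- object$month_effects[newdata$month]
  if (anyNA(eff)) {
    stop("prediction requested for a month absent from the fitting data",
         call. = FALSE)
  }
  object$coefficients["beta0"] + object$coefficients["beta1"] * newdata$sst_c +
    unname(eff)
}

#' Monthly heat-stress probability with 15-day saturation
#'
#' The probability that a month constitutes a heat-stress month: 1 when the
#' number of heat-stress days reaches the saturation count (default 15, i.e.
#' half a month of stress is treated as a full stress month), otherwise the
#' fraction of stress days `z / n`.
#'
#' @param z Number of heat-stress days in the month (vectorised).
#' @param n Number of days in the month.
#' @param saturation_days Day count at which the probability saturates at 1.
#' @return Probabilities in `[0, 1]`.
#' @export
monthly_heat_stress_probability <- function(z, n, saturation_days = 15) {
  stopifnot(all(z >= 0), all(n > 0), all(z <= n))
  ifelse(z >= saturation_days, 1, z / n)
}

days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  nxt <- as.Date(ifelse(month == 12, sprintf("%d-01-01", year + 1),
                        sprintf("%d-%02d-01", year, month + 1)))
  as.integer(nxt - first)
}

#' Project monthly evidence probabilities from daily SST
#'
#' Applies the fitted thermal-optimality and daily-maximum models to a
#' projected daily mean SST series and aggregates to calendar months: the
#' monthly sub-optimal probability is the mean of the predicted daily
#' sub-optimality probabilities; the heat-stress day count is the number of
#' days whose predicted maximum meets the mortality threshold; the monthly
#' heat-stress probability follows the saturating rule of
#' [monthly_heat_stress_probability()].
#'
#' @param opt_model A `thermal_optimality_model`.
#' @param max_model A `max_temp_model`.
#' @param projected_sst Data.frame `date`, `sst_c` covering whole calendar
#'   months (a 365-day calendar February of 28 days in a leap year counts as
#'   whole).
#' @param mortality_threshold Shoot-mortality threshold (degC).
#' @param saturation_days Saturation count for the monthly rule.
#' @param allow_partial Permit partial months (otherwise an error).
#' @param residual_noise If `TRUE`, add Gaussian noise with the fitted residual
#'   SD to predicted maxima (off by default: projection is deterministic).
#' @param seed Seed used only when `residual_noise = TRUE`.
#' @return Data.frame `year`, `month`, `n_days`, `p_suboptimal`, `z_t`,
#'   `p_heatstress`.
#' @export
project_monthly_probabilities <- function(opt_model, max_model, projected_sst,
                                          mortality_threshold = 30,
                                          saturation_days = 15,
                                          allow_partial = FALSE,
                                          residual_noise = FALSE,
                                          seed = NULL) {
  stopifnot(inherits(opt_model, "thermal_optimality_model"),
            inherits(max_model, "max_temp_model"))
  d <- projected_sst[, c("date", "sst_c")]
  d$date <- as.Date(d$date)
  d$year <- date_year(d$date)
  d$month <- date_month(d$date)
  d$p_d <- predict(opt_model, d$sst_c)
  d$y_hat <- predict(max_model, d)
  if (residual_noise) {
    noise <- if (is.null(seed)) {
      stats::rnorm(nrow(d), 0, max_model$residual_sd)
    } else {
      with_private_seed(seed, stats::rnorm(nrow(d), 0, max_model$residual_sd))
    }
    d$y_hat <- d$y_hat + noise
  }
  key <- interaction(d$year, d$month, drop = TRUE)
  agg <- do.call(rbind, lapply(split(d, key), function(g) {
    data.frame(year = g$year[1], month = g$month[1], n_days = nrow(g),
               p_suboptimal = mean(g$p_d),
               z_t = sum(g$y_hat >= mortality_threshold))
  }))
  agg <- agg[order(agg$year, agg$month), ]
  expected <- days_in_month(agg$year, agg$month)
  whole <- agg$n_days == expected | (agg$month == 2 & agg$n_days == 28)
  if (!all(whole) && !allow_partial) {
    bad <- agg[!whole, ]
    stop(sprintf("partial month(s): %s (use allow_partial = TRUE to accept)",
                 paste(sprintf("%d-%02d", bad$year, bad$month), collapse = ", ")),
         call. = FALSE)
  }
  agg$p_heatstress <- monthly_heat_stress_probability(agg$z_t, agg$n_days,
                                                      saturation_days)
  rownames(agg) <- NULL
  agg
}

#' Write monthly probabilities to CSV
#'
#' Columns `year,month,n_days,p_suboptimal,z_t,p_heatstress`.
#' @param x Output of [project_monthly_probabilities()].
#' @param path File path.
#' @export
write_monthly_probabilities_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
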