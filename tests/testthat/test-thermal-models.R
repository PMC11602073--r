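test_that("daily optimality labelling follows the all-readings rule", {
  mk_day <- function(date, temps) {
    data.frame(timestamp = as.POSIXct(date, tz = "UTC") +
                 seq(0, by = 1800, length.out = length(temps)),
               temp_c = temps)
  }
  hf <- rbind(mk_day("2022-06-01", rep(23, 48)),        # all below
              mk_day("2022-06-02", c(rep(23, 47), 23.9)), # max 23.9 -> optimal
              mk_day("2022-06-03", 24.1),               # single reading above
              mk_day("2022-06-04", rep(24, 48)))        # boundary: <= is optimal
  lab <- label_daily_optimality(hf, 24)
  expect_equal(lab$suboptimal, c(FALSE, FALSE, TRUE, FALSE))
  # a day of NA readings is skipped with a warning
  hf_na <- rbind(hf, mk_day("2022-06-05", rep(NA_real_, 4)))
  expect_warning(lab2 <- label_daily_optimality(hf_na, 24), "skipped")
  expect_equal(nrow(lab2), 4)
})

test_that("daily maxima flag heat-stress days at the threshold", {
  hf <- data.frame(
    timestamp = as.POSIXct("2022-01-01", tz = "UTC") + seq(0, by = 1800,
                                                           length.out = 96),
    temp_c = c(seq(25, 29.99, length.out = 48), seq(26, 30, length.out = 48)))
  dm <- daily_maxima(hf, 30)
  expect_equal(dm$heat_stress, c(FALSE, TRUE))  # >= 30 is stress
})

test_that("logistic fit recovers known coefficients and McFadden R2", {
  w <- simulate_thermal_world(sigma = 0.1, seed = 11)
  fit <- fit_optimality_model(w$labels, w$sst)
  ci <- suppressMessages(confint.default(fit$fit))
  expect_gt(w$b[1], ci[1, 1]); expect_lt(w$b[1], ci[1, 2])
  expect_gt(w$b[2], ci[2, 1]); expect_lt(w$b[2], ci[2, 2])
  # McFadden R2 against an independent likelihood evaluation
  d <- merge(w$labels, w$sst[, c("date", "sst_c")], by = "date")
  eta <- fit$coefficients[1] + fit$coefficients[2] * d$sst_c
  ll <- sum(ifelse(d$suboptimal, stats::plogis(eta),
                   1 - stats::plogis(eta)) |> log())
  p0 <- mean(d$suboptimal)
  ll0 <- sum(d$suboptimal) * log(p0) + sum(!d$suboptimal) * log(1 - p0)
  expect_equal(fit$mcfadden_r2, 1 - ll / ll0, tolerance = 1e-10)
  expect_true(fit$mcfadden_r2 > 0 && fit$mcfadden_r2 < 1)
})

test_that("logistic fit fails loudly on degenerate inputs", {
  w <- simulate_thermal_world(seed = 3)
  all_sub <- transform(w$labels, suboptimal = TRUE)
  expect_error(fit_optimality_model(all_sub, w$sst), "one optimality class")
  # perfect separation: label purely by threshold on the predictor
  sep <- transform(w$labels, suboptimal = NULL)
  sep$suboptimal <- w$sst$sst_c[match(sep$date, w$sst$date)] > 24
  expect_error(fit_optimality_model(sep, w$sst), "separation")
  expect_error(fit_optimality_model(w$labels[1:10, ], w$sst), "30")
})

test_that("noise-free linear data is interpolated exactly", {
  w <- simulate_thermal_world(sigma = 0, seed = 5)
  fit <- fit_max_temp_model(w$maxima, w$sst)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["beta1"]), w$a[2], tolerance = 1e-8)
  # categorical effects are relative to the reference month
  eff <- fit$month_effects - fit$month_effects[1]
  expect_equal(eff, w$month_eff - w$month_eff[1], tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["beta0"]), w$a[1] + w$month_eff[1],
               tolerance = 1e-8)
})

test_that("noisy linear fit recovers coefficients within 3 SE", {
  w <- simulate_thermal_world(sigma = 0.1, seed = 9)
  fit <- fit_max_temp_model(w$maxima, w$sst)
  expect_gte(fit$r2, 0.99)
  se <- coef(summary(fit$fit))["sst_c", "Std. Error"]
  expect_lt(abs(fit$coefficients["beta1"] - w$a[2]), 3 * se)
  expect_lt(abs(fit$residual_sd - w$sigma), 0.02)
})

test_that("max-temp fit validates its inputs and encodings", {
  w <- simulate_thermal_world(seed = 2)
  jan <- w$maxima[format(w$maxima$date, "%m") == "01", ]
  expect_error(fit_max_temp_model(jan, w$sst), "2 distinct months")
  few <- w$maxima[1:30, ]
  expect_error(fit_max_temp_model(few, w$sst), "60")
  num <- fit_max_temp_model(w$maxima, w$sst, month_encoding = "numeric")
  expect_equal(num$month_encoding, "numeric")
  expect_equal(num$month_effects / (1:12), rep(num$month_effects[1], 12))
})

test_that("monthly heat-stress probability saturates at 15 days", {
  expect_identical(monthly_heat_stress_probability(16, 30), 1)
  expect_identical(monthly_heat_stress_probability(15, 30), 1)
  expect_equal(monthly_heat_stress_probability(6, 30), 0.2)
  expect_equal(monthly_heat_stress_probability(0:14, 30), (0:14) / 30)
  expect_error(monthly_heat_stress_probability(31, 30))
})

test_that("monthly projection aggregates daily predictions", {
  opt <- make_opt_model(-30, 1.3)
  mx <- make_max_model(0.4, 1)  # y_hat = sst + 0.4
  # June 2030: predicted maxima reach 30 on exactly 6 of 30 days
  sst <- data.frame(date = seq(as.Date("2030-06-01"), by = "day",
                               length.out = 30),
                    sst_c = c(rep(29.6, 6), rep(28, 24)))
  out <- project_monthly_probabilities(opt, mx, sst)
  expect_equal(out$z_t, 6)
  expect_equal(out$p_heatstress, 0.2)
  expect_equal(out$p_suboptimal,
               mean(plogis(-30 + 1.3 * sst$sst_c)))
  # 16 of 30 days at/above threshold saturates to 1
  sst$sst_c[1:16] <- 29.6; sst$sst_c[17:30] <- 28
  expect_equal(project_monthly_probabilities(opt, mx, sst)$p_heatstress, 1)
  # all p_d ~ 0 -> p_t ~ 0
  cold <- transform(sst, sst_c = 0)
  expect_lt(project_monthly_probabilities(opt, mx, cold)$p_suboptimal, 1e-12)
})

test_that("toy 3-day month averages the daily probabilities", {
  opt <- make_opt_model(0, 1)  # p = plogis(sst)
  mx <- make_max_model(0, 1)
  p_target <- c(0.1, 0.2, 0.6)
  sst <- data.frame(date = as.Date("2030-06-01") + 0:2,
                    sst_c = qlogis(p_target))
  expect_error(project_monthly_probabilities(opt, mx, sst), "partial")
  out <- project_monthly_probabilities(opt, mx, sst, allow_partial = TRUE)
  expect_equal(out$p_suboptimal, 0.3)
})

test_that("warming never lowers monthly stress probabilities", {
  opt <- make_opt_model(-30, 1.3)
  mx <- make_max_model(1, 1.02, month_effects = seq(0, 1.1, by = 0.1))
  sst <- generate_daily_sst(gladstone_params(noise_sd = 0.5, ar1_rho = 0.7),
                            2030:2031, seed = 21)
  base <- project_monthly_probabilities(opt, mx, sst)
  for (shift in c(0.5, 1, 2)) {
    warm <- transform(sst, sst_c = sst_c + shift)
    up <- project_monthly_probabilities(opt, mx, warm)
    expect_true(all(up$p_suboptimal >= base$p_suboptimal - 1e-12))
    expect_true(all(up$p_heatstress >= base$p_heatstress - 1e-12))
  }
  expect_true(all(base$p_suboptimal >= 0 & base$p_suboptimal <= 1))
  expect_true(all(base$p_heatstress >= 0 & base$p_heatstress <= 1))
})

test_that("McFadden R2 is invariant to shifting the predictor", {
  w <- simulate_thermal_world(sigma = 0.1, seed = 13)
  f1 <- fit_optimality_model(w$labels, w$sst)
  shifted <- transform(w$sst, sst_c = sst_c + 5)
  f2 <- fit_optimality_model(w$labels, shifted)
  expect_equal(f1$mcfadden_r2, f2$mcfadden_r2, tolerance = 1e-8)
})
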