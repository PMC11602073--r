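# Minimal trajectory builder: monthly probabilities for one node
mk_traj <- function(years, p_by_state, node = "shoot_density") {
  states <- names(p_by_state)
  months <- expand.grid(month = 1:12, year = years)
  do.call(rbind, lapply(states, function(s) {
    p <- rep(p_by_state[[s]], length.out = nrow(months))
    data.frame(year = months$year, month = months$month, slice = seq_len(nrow(months)),
               node = node, state = s, probability = p)
  }))
}

mk_cycle <- function(p_by_state, node = "shoot_density") {
  x <- mk_traj(2022, p_by_state, node)
  x$year <- NA_integer_
  x
}

test_that("ratios are trajectory over baseline by month-of-year", {
  base <- mk_cycle(list(high = 0.6, zero = 0.1))
  traj <- mk_traj(2030:2031, list(high = 0.3, zero = 0.2))
  r <- ratio_series(traj, base)
  expect_equal(unique(r$ratio[r$state == "high"]), 0.5)
  expect_equal(unique(r$ratio[r$state == "zero"]), 2)
  # identity: a trajectory against itself is 1 everywhere
  self <- mk_traj(2022, list(high = seq(0.2, 0.9, length.out = 12)))
  cyc <- self; cyc$year <- NA_integer_
  r1 <- ratio_series(self, cyc)
  expect_true(all(abs(r1$ratio - 1) < 1e-12))
  # baseline zero -> missing with warning, never capped
  base0 <- mk_cycle(list(high = c(0, rep(0.5, 11))))
  tr <- mk_traj(2030, list(high = 0.4))
  expect_warning(rz <- ratio_series(tr, base0), "undefined")
  expect_true(is.na(rz$ratio[rz$month == 1]))
  expect_equal(rz$ratio[rz$month == 2], 0.8)
})

test_that("annualization averages months and handles gaps", {
  m <- data.frame(year = 2030, month = 1:12, state = "high", ratio = 0.7)
  a <- annualize(m)
  expect_equal(a$ratio, 0.7)
  expect_false(a$partial)
  # 12 distinct values -> arithmetic mean
  vals <- seq(0.1, 1.2, by = 0.1)
  m2 <- transform(m, ratio = vals)
  expect_equal(annualize(m2)$ratio, sum(vals) / 12)
  # bounded by the monthly extremes
  expect_gte(annualize(m2)$ratio, min(vals))
  expect_lte(annualize(m2)$ratio, max(vals))
  # one missing month -> mean of 11, flagged partial
  m3 <- m2; m3$ratio[5] <- NA
  a3 <- annualize(m3)
  expect_equal(a3$ratio, mean(vals[-5]))
  expect_true(a3$partial)
  expect_equal(a3$n_months, 11)
  # all months missing -> missing annual value
  m4 <- transform(m, ratio = NA_real_)
  expect_true(is.na(annualize(m4)$ratio))
  # whole-year enforcement
  expect_error(annualize(m2[1:7, ]), "partial calendar year")
})

test_that("the fall-and-return rule reproduces the worked trace", {
  a <- data.frame(year = 2030:2033, ratio = c(1.0, 0.8, 0.85, 0.95))
  ev <- recovery_times(a, 0.9)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$y, 2031)
  expect_equal(ev$y_prime, 2033)
  expect_equal(ev$q, 2)
  expect_false(ev$censored)
  # never below -> no events
  expect_equal(nrow(recovery_times(transform(a, ratio = 1), 0.9)), 0)
  # drops and never returns -> censored
  cens <- recovery_times(data.frame(year = 2030:2034,
                                    ratio = c(1, 0.5, 0.4, 0.3, 0.2)), 0.9)
  expect_equal(nrow(cens), 1)
  expect_true(cens$censored)
  expect_true(is.na(cens$q))
  # short series -> empty
  expect_equal(nrow(recovery_times(a[1, ], 0.9)), 0)
  # multiple disjoint, ordered events with q >= 1
  multi <- data.frame(year = 2030:2039,
                      ratio = c(1, 0.5, 1, 1, 0.6, 0.6, 1, 0.7, 0.95, 1))
  evm <- recovery_times(multi, 0.9)
  expect_equal(evm$y, c(2031, 2034, 2037))
  expect_equal(evm$q, c(1, 2, 1))
  expect_true(all(evm$q >= 1))
  expect_true(all(diff(evm$y) > 0))
})

test_that("inter-event summary reproduces the worked gap accounting", {
  yrs <- 2030:2045
  ratio <- rep(0.5, length(yrs))
  ratio[yrs %in% c(2030, 2031, 2033, 2045)] <- 0.95
  a <- data.frame(year = yrs, ratio = ratio)
  s <- interevent_summary(a, 0.9)
  expect_equal(s$event_years, c(2030, 2031, 2033, 2045))
  expect_equal(s$intervals, c(1, 2, 12))
  expect_equal(s$mean_recovery, 5.0)
  expect_equal(s$max_gap, 12)
  expect_equal(s$n_instances, 4)
  # interval accounting: sum of gaps spans first to last event
  expect_equal(sum(s$intervals), max(s$event_years) - min(s$event_years))
  # single event year: no intervals, missing mean/max
  one <- data.frame(year = 2030:2034, ratio = c(0.95, 0.5, 0.5, 0.5, 0.5))
  s1 <- interevent_summary(one, 0.9)
  expect_equal(s1$n_instances, 1)
  expect_true(is.na(s1$mean_recovery))
  expect_true(is.na(s1$max_gap))
  # all years at threshold: n events = n years, all gaps 1
  all10 <- data.frame(year = 2030:2039, ratio = 1)
  s10 <- interevent_summary(all10, 0.9)
  expect_equal(s10$n_instances, 10)
  expect_true(all(s10$intervals == 1))
  expect_equal(s10$mean_recovery, 1)
  # no event years at all
  none <- data.frame(year = 2030:2039, ratio = 0.1)
  s0 <- interevent_summary(none, 0.9)
  expect_equal(s0$n_instances, 0)
  expect_true(is.na(s0$mean_recovery))
})

test_that("lowering the threshold never loses recovery instances", {
  set.seed(31)
  for (i in 1:20) {
    a <- data.frame(year = 2030:2059, ratio = runif(30, 0.5, 1.1))
    n9 <- interevent_summary(a, 0.9)$n_instances
    n8 <- interevent_summary(a, 0.8)$n_instances
    expect_gte(n8, n9)
  }
})

test_that("permanent loss triggers on gaps strictly above the limit", {
  yrs <- 2030:2045
  ratio <- rep(0.5, length(yrs))
  ratio[yrs %in% c(2030, 2031, 2033, 2045)] <- 0.95
  s <- interevent_summary(data.frame(year = yrs, ratio = ratio), 0.9)
  expect_true(flag_permanent_loss(s, 5))     # max gap 12 > 5
  # max gap exactly 5 does not trigger
  r5 <- rep(0.5, 11); r5[c(1, 6, 11)] <- 1
  s5 <- interevent_summary(data.frame(year = 2030:2040, ratio = r5), 0.9)
  expect_equal(s5$max_gap, 5)
  expect_false(flag_permanent_loss(s5, 5))
  # never below threshold -> not flagged
  ok <- interevent_summary(data.frame(year = 2030:2040, ratio = 1), 0.9)
  expect_false(flag_permanent_loss(ok, 5))
  # censored tail longer than the limit triggers even with small gaps
  rc <- c(1, 1, rep(0.5, 9))
  sc <- interevent_summary(data.frame(year = 2030:2040, ratio = rc), 0.9)
  expect_true(flag_permanent_loss(sc, 5))
})

test_that("prediction intervals follow the interpolated-percentile convention", {
  # constant samples collapse every statistic
  const <- data.frame(year = 2030, ratio = rep(0.8, 50))
  s <- prediction_intervals(const)
  expect_equal(unlist(s[, c("mean", "q05", "q25", "q75", "q95")]),
               rep(0.8, 5), ignore_attr = TRUE)
  # samples 1..100 against an independent sort-and-interpolate computation
  x <- sample(1:100)
  s2 <- prediction_intervals(data.frame(year = 2030, ratio = x))
  manual_pct <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  expect_equal(s2$q05, manual_pct(x, 0.05))
  expect_equal(s2$q95, manual_pct(x, 0.95))
  expect_equal(s2$q25, manual_pct(x, 0.25))
  expect_equal(s2$q75, manual_pct(x, 0.75))
  # nesting: 50% interval inside 90% interval, any sample set
  set.seed(77)
  for (i in 1:10) {
    r <- data.frame(year = rep(2030:2034, each = 20), ratio = rlnorm(100))
    si <- prediction_intervals(r)
    expect_true(all(si$q05 <= si$q25 + 1e-12))
    expect_true(all(si$q25 <= si$q75 + 1e-12))
    expect_true(all(si$q75 <= si$q95 + 1e-12))
  }
})

test_that("interval widths difference the percentile bounds", {
  s <- data.frame(year = 2030, q05 = 0.1, q25 = 0.3, q75 = 0.5, q95 = 0.9)
  w <- interval_widths(s)
  expect_equal(w$width90, 0.8)
  expect_equal(w$width50, 0.2)
})
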