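#' Baseline-relative monthly state ratios
#'
#' For each month and state of the chosen node, the ratio of the trajectory's
#' marginal probability to the baseline cycle's probability for the same
#' month-of-year: `r_S(t) = p_S(t) / p_S^B(month(t))`. Baseline probabilities
#' of zero yield missing ratios with a warning (no capping), so downstream
#' summaries stay honest about undefined ratios.
#'
#' @param traj A `state_trajectory` with `year` and `month` columns (scenario
#'   run).
#' @param baseline A `state_trajectory` holding one 12-month baseline cycle
#'   (a `month` column with months 1-12).
#' @param node Node whose states are ratioed (default `"shoot_density"`).
#' @return Data.frame `year`, `month`, `state`, `ratio`.
#' @export
ratio_series <- function(traj, baseline, node = "shoot_density") {
  tr <- traj[traj$node == node, ]
  bl <- baseline[baseline$node == node, ]
  if (!nrow(tr) || !nrow(bl)) {
    stop(sprintf("node '%s' absent from trajectory or baseline", node),
         call. = FALSE)
  }
  if (!all(1:12 %in% bl$month)) {
    stop("baseline cycle must cover all 12 months of the year", call. = FALSE)
  }
  key_b <- paste(bl$month, bl$state)
  pb <- stats::setNames(bl$probability, key_b)
  denom <- pb[paste(tr$month, tr$state)]
  zero <- !is.na(denom) & denom == 0
  if (any(zero)) {
    warning(sprintf("%d ratio(s) undefined (baseline probability 0); set NA",
                    sum(zero)), call. = FALSE)
  }
  ratio <- ifelse(zero, NA_real_, tr$probability / denom)
  out <- data.frame(year = tr$year, month = tr$month, state = tr$state,
                    ratio = as.numeric(ratio))
  out <- out[order(out$state, out$year, out$month), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annualize monthly ratios
#'
#' The annual ratio of a year is the arithmetic mean of its monthly ratios.
#' Months with missing ratios are excluded with the divisor adjusted and the
#' year flagged partial; a year with all twelve months missing gets a missing
#' annual value.
#'
#' @param monthly Output of [ratio_series()] (columns `year`, `state`,
#'   `ratio`; optionally `month`).
#' @param require_whole_years Error unless every (year, state) group has 12
#'   months of data (missing ratios still allowed).
#' @return Data.frame `year`, `state`, `ratio`, `n_months`, `partial`.
#' @export
annualize <- function(monthly, require_whole_years = TRUE) {
  stopifnot(all(c("year", "state", "ratio") %in% names(monthly)))
  grp <- interaction(monthly$year, monthly$state, drop = TRUE)
  if (require_whole_years) {
    sizes <- tapply(monthly$ratio, grp, length)
    if (any(sizes != 12)) {
      stop("partial calendar year(s) present; set require_whole_years = FALSE",
           call. = FALSE)
    }
  }
  out <- do.call(rbind, lapply(split(monthly, grp), function(g) {
    ok <- !is.na(g$ratio)
    data.frame(year = g$year[1], state = g$state[1],
               ratio = if (any(ok)) mean(g$ratio[ok]) else NA_real_,
               n_months = sum(ok), partial = sum(ok) < nrow(g))
  }))
  out <- out[order(out$state, out$year), ]
  rownames(out) <- NULL
  out
}

#' Recovery events under the fall-and-return rule
#'
#' Scans an annual ratio series for recovery events: `y` is the first year of
#' a maximal run of years with ratio below the threshold (entered from a year
#' at/above it, or from the series start), `y'` the first subsequent year at
#' or above the threshold, and the recovery time is `q = y' - y`. A dip with
#' no return before the series end yields a censored event.
#'
#' @param annual Data.frame with columns `year` and `ratio` (one state's
#'   annual series, ordered or orderable by year). Missing ratios are dropped.
#' @param threshold Recovery threshold in `(0, 1]` (default 0.9: 90% of
#'   baseline).
#' @return Data.frame `y`, `y_prime`, `q`, `threshold`, `censored`; zero rows
#'   when no event occurs or the series is shorter than 2 years.
#' @export
recovery_times <- function(annual, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1,
            all(c("year", "ratio") %in% names(annual)))
  a <- annual[!is.na(annual$ratio), c("year", "ratio")]
  a <- a[order(a$year), ]
  empty <- data.frame(y = integer(0), y_prime = integer(0), q = integer(0),
                      threshold = numeric(0), censored = logical(0))
  if (nrow(a) < 2) return(empty)
  below <- a$ratio < threshold
  ev <- list()
  i <- 1L
  n <- nrow(a)
  while (i <= n) {
    if (below[i] && (i == 1L || !below[i - 1L])) {
      j <- i
      while (j <= n && below[j]) j <- j + 1L
      if (j <= n) {
        ev[[length(ev) + 1L]] <- data.frame(
          y = a$year[i], y_prime = a$year[j], q = a$year[j] - a$year[i],
          threshold = threshold, censored = FALSE)
      } else {
        ev[[length(ev) + 1L]] <- data.frame(
          y = a$year[i], y_prime = NA_integer_, q = NA_integer_,
          threshold = threshold, censored = TRUE)
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(ev)) return(empty)
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Inter-event recovery summary
#'
#' Treats every year whose annual ratio is at or above the threshold as a
#' recovery event; gaps are the differences between consecutive event years.
#' Reports the mean gap ("mean recovery time"), the maximum gap, and the
#' event count, plus the open trailing gap from the last event to the period
#' end (the whole period length when no event occurs). The interval from the
#' period start to the first event is excluded by default.
#'
#' @inheritParams recovery_times
#' @param period Length-2 year range; defaults to the series range.
#' @param include_first_interval Also count the gap from `period[1]` to the
#'   first event year.
#' @return Object of class `recovery_summary`: a list with `event_years`,
#'   `intervals`, `mean_recovery`, `max_gap`, `n_instances`, `trailing_gap`,
#'   `threshold`, `period`.
#' @export
interevent_summary <- function(annual, threshold = 0.9, period = NULL,
                               include_first_interval = FALSE) {
  stopifnot(all(c("year", "ratio") %in% names(annual)))
  a <- annual[!is.na(annual$ratio), c("year", "ratio")]
  a <- a[order(a$year), ]
  if (is.null(period)) period <- range(a$year)
  ev_years <- a$year[a$ratio >= threshold]
  intervals <- if (length(ev_years) >= 2) diff(ev_years) else integer(0)
  if (include_first_interval && length(ev_years) >= 1) {
    intervals <- c(ev_years[1] - period[1], intervals)
  }
  trailing <- if (length(ev_years)) period[2] - max(ev_years)
              else diff(period)
  structure(list(
    event_years = ev_years,
    intervals = intervals,
    mean_recovery = if (length(intervals)) mean(intervals) else NA_real_,
    max_gap = if (length(intervals)) max(intervals) else NA_integer_,
    n_instances = length(ev_years),
    trailing_gap = as.integer(trailing),
    threshold = threshold, period = period
  ), class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Recovery summary (threshold %.2f, %d-%d):\n",
              x$threshold, x$period[1], x$period[2]))
  cat(sprintf("  %d recovery instance(s); mean recovery %s yr; max gap %s yr; trailing gap %d yr\n",
              x$n_instances,
              if (is.na(x$mean_recovery)) "NA" else sprintf("%.2f", x$mean_recovery),
              if (is.na(x$max_gap)) "NA" else sprintf("%d", x$max_gap),
              x$trailing_gap))
  invisible(x)
}

#' Permanent-loss flag
#'
#' A meadow that fails to recover within the limit (default five years) is
#' treated as permanently lost: flagged when any inter-event gap, or the open
#' trailing gap to the series end, strictly exceeds `limit_years`.
#'
#' @param summary A [interevent_summary()] result.
#' @param limit_years Loss limit in years.
#' @return Logical flag.
#' @export
flag_permanent_loss <- function(summary, limit_years = 5) {
  stopifnot(inherits(summary, "recovery_summary"))
  gap <- suppressWarnings(max(c(summary$intervals, summary$trailing_gap)))
  isTRUE(gap > limit_years)
}

#' Monte Carlo prediction intervals per year
#'
#' Percentile prediction intervals across Monte Carlo samples of annual
#' ratios: the 90% interval spans the 5th-95th percentiles and the 50%
#' interval the 25th-75th, under the linear-interpolation percentile
#' convention (`stats::quantile` type 7). Years with fewer than two samples
#' get missing bounds.
#'
#' @param samples Data.frame with columns `year` and `ratio` (all Monte Carlo
#'   samples of one state pooled; missing ratios dropped).
#' @return Object of class `ensemble_summary`: data.frame `year`, `n`, `mean`,
#'   `q05`, `q25`, `q75`, `q95`.
#' @export
prediction_intervals <- function(samples) {
  stopifnot(all(c("year", "ratio") %in% names(samples)))
  s <- samples[!is.na(samples$ratio), ]
  out <- do.call(rbind, lapply(split(s, s$year), function(g) {
    if (nrow(g) < 2) {
      return(data.frame(year = g$year[1], n = nrow(g),
                        mean = if (nrow(g)) mean(g$ratio) else NA_real_,
                        q05 = NA_real_, q25 = NA_real_,
                        q75 = NA_real_, q95 = NA_real_))
    }
    qs <- stats::quantile(g$ratio, c(0.05, 0.25, 0.75, 0.95),
                          names = FALSE, type = 7)
    data.frame(year = g$year[1], n = nrow(g), mean = mean(g$ratio),
               q05 = qs[1], q25 = qs[2], q75 = qs[3], q95 = qs[4])
  }))
  out <- out[order(out$year), ]
  rownames(out) <- NULL
  structure(out, class = c("ensemble_summary", "data.frame"))
}

#' Prediction-interval widths
#'
#' Widths of the 90% (5th-95th percentile) and 50% (25th-75th percentile)
#' prediction intervals of an ensemble summary, e.g. to compare forecast
#' uncertainty across years or scenarios.
#'
#' @param summary An [prediction_intervals()] result, or any data.frame with
#'   `q05`, `q25`, `q75`, `q95` columns.
#' @return Data.frame `year` (when present), `width90`, `width50`.
#' @export
interval_widths <- function(summary) {
  stopifnot(all(c("q05", "q25", "q75", "q95") %in% names(summary)))
  out <- data.frame(width90 = summary$q95 - summary$q05,
                    width50 = summary$q75 - summary$q25)
  if ("year" %in% names(summary)) out <- cbind(year = summary$year, out)
  out
}

#' Ribbon plot of annual ratio prediction intervals
#'
#' Base-graphics plot of the ensemble mean with shaded 50% and 90% prediction
#' bands, the usual display for Monte Carlo ratio trajectories.
#'
#' @param x An `ensemble_summary`.
#' @param main,ylab,xlab Usual graphical labels.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ensemble_summary <- function(x, main = "Annual ratio",
                                  ylab = "ratio vs baseline",
                                  xlab = "year", ...) {
  ok <- stats::complete.cases(x[, c("q05", "q95")])
  graphics::plot(x$year, x$mean, type = "n",
                 ylim = range(c(x$q05[ok], x$q95[ok], x$mean), na.rm = TRUE),
                 main = main, xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(x$year[ok], rev(x$year[ok])),
                    c(x$q05[ok], rev(x$q95[ok])),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::polygon(c(x$year[ok], rev(x$year[ok])),
                    c(x$q25[ok], rev(x$q75[ok])),
                    col = grDevices::adjustcolor("steelblue", 0.45),
                    border = NA)
  graphics::lines(x$year, x$mean, lwd = 2)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
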