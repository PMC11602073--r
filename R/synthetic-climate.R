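# Run code with a private RNG stream so callers' .Random.seed is untouched.
with_private_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# Sequence of calendar dates over whole years; "noleap" drops Feb 29 to mirror
# the 365-day calendars used by many climate models.
year_dates <- function(years, calendar = c("gregorian", "noleap")) {
  calendar <- match.arg(calendar)
  d <- seq(as.Date(sprintf("%d-01-01", min(years))),
           as.Date(sprintf("%d-12-31", max(years))), by = "day")
  if (calendar == "noleap") {
    d <- d[!(format(d, "%m-%d") == "02-29")]
  }
  d
}

date_year  <- function(d) as.integer(format(d, "%Y"))
date_month <- function(d) as.integer(format(d, "%m"))

#' Scenario parameters for the synthetic daily SST generator
#'
#' Bundles the statistical description of one climate scenario: a seasonal
#' sinusoid (annual-mean SST, amplitude, peak month), a piecewise-linear
#' warming path, and an AR(1) daily noise process shared by all ensemble
#' members.
#'
#' @param scenario_name Label, e.g. `"SSP5-8.5"`.
#' @param mean_sst Annual-mean SST in degrees Celsius.
#' @param seasonal_amplitude Half-range of the seasonal cycle (deg C, >= 0).
#' @param peak_month Calendar month (1-12) at which the seasonal cycle peaks.
#' @param warming_knots Two-column matrix or data.frame `(year, delta_t)` of
#'   strictly increasing years defining a piecewise-linear warming path in
#'   degrees Celsius added to the seasonal climatology. Values outside the knot
#'   range are held at the nearest knot.
#' @param ar1_rho Lag-1 autocorrelation of daily noise, `|ar1_rho| < 1`.
#' @param noise_sd Stationary (marginal) standard deviation of the daily AR(1)
#'   noise in degrees Celsius (>= 0). The innovation SD is
#'   `noise_sd * sqrt(1 - ar1_rho^2)`.
#' @param n_members Number of ensemble members (>= 1).
#'
#' @return An object of class `scenario_params`.
#' @seealso [gladstone_params()], [generate_daily_sst()]
#' @export
scenario_params <- function(scenario_name, mean_sst, seasonal_amplitude,
                            peak_month, warming_knots = NULL,
                            ar1_rho = 0, noise_sd = 0, n_members = 1L) {
  if (is.null(warming_knots)) {
    warming_knots <- data.frame(year = c(2015, 2100), delta_t = c(0, 0))
  }
  warming_knots <- as.data.frame(warming_knots)
  names(warming_knots) <- c("year", "delta_t")
  stopifnot(
    is.character(scenario_name), length(scenario_name) == 1L,
    is.finite(mean_sst), seasonal_amplitude >= 0,
    peak_month %in% 1:12,
    noise_sd >= 0, abs(ar1_rho) < 1, n_members >= 1
  )
  if (nrow(warming_knots) < 1 || any(diff(warming_knots$year) <= 0)) {
    stop("warming_knots must have strictly increasing years", call. = FALSE)
  }
  structure(list(
    scenario_name = scenario_name, mean_sst = mean_sst,
    seasonal_amplitude = seasonal_amplitude, peak_month = as.integer(peak_month),
    warming_knots = warming_knots, ar1_rho = ar1_rho, noise_sd = noise_sd,
    n_members = as.integer(n_members)
  ), class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat(sprintf("Scenario '%s': mean %.2f degC, amplitude %.2f, peak month %d\n",
              x$scenario_name, x$mean_sst, x$seasonal_amplitude, x$peak_month))
  cat(sprintf("  AR(1) rho %.2f, noise sd %.2f degC, %d member(s)\n",
              x$ar1_rho, x$noise_sd, x$n_members))
  kn <- x$warming_knots
  cat("  warming path:",
      paste(sprintf("%d:%+.2f", kn$year, kn$delta_t), collapse = " "), "\n")
  invisible(x)
}

#' Gladstone Harbour climatology preset
#'
#' Scenario parameters matching the study site's SST climatology: minimum
#' 19.2 degC in August, maximum 29.7 degC in January, annual mean 24.4 degC
#' (amplitude 5.25, peak in January).
#'
#' @inheritParams scenario_params
#' @param scenario_name Label for the series.
#' @return An object of class `scenario_params`.
#' @export
gladstone_params <- function(scenario_name = "historical", warming_knots = NULL,
                             ar1_rho = 0.8, noise_sd = 0.5, n_members = 1L) {
  scenario_params(scenario_name, mean_sst = 24.4, seasonal_amplitude = 5.25,
                  peak_month = 1L, warming_knots = warming_knots,
                  ar1_rho = ar1_rho, noise_sd = noise_sd, n_members = n_members)
}

# Piecewise-linear warming path evaluated at (integer) calendar years,
# constant outside the knot range.
warming_at <- function(params, years) {
  kn <- params$warming_knots
  if (nrow(kn) == 1L) return(rep(kn$delta_t, length(years)))
  stats::approx(kn$year, kn$delta_t, xout = years, rule = 2)$y
}

#' Generate synthetic daily sea-surface temperatures
#'
#' Each ensemble member is the sum of a seasonal cosine centred on the
#' scenario's mean SST, the scenario warming path (evaluated per calendar
#' year), and stationary AR(1) noise. Output is bit-identical for identical
#' `(params, years, seed)`; member `m` uses the substream seed
#' `bitwXor(seed, m)`.
#'
#' @param params A [scenario_params()] object.
#' @param years Integer vector of calendar years (need not be contiguous;
#'   whole years are always generated).
#' @param seed Integer study seed.
#' @param calendar `"gregorian"` (real dates incl. leap days) or `"noleap"`
#'   (365-day model calendar).
#' @return A data.frame with columns `date`, `scenario`, `member`, `sst_c`,
#'   one row per day per member. The per-member substream seeds are attached
#'   as attribute `"member_seeds"`.
#' @examples
#' p <- gladstone_params(noise_sd = 0, ar1_rho = 0)
#' sst <- generate_daily_sst(p, 2022, seed = 1)
#' range(sst$sst_c) # approx 19.2 .. 29.7
#' @export
generate_daily_sst <- function(params, years, seed,
                               calendar = c("gregorian", "noleap")) {
  stopifnot(inherits(params, "scenario_params"))
  if (length(years) == 0L) stop("empty year range", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  calendar <- match.arg(calendar)
  years <- sort(unique(as.integer(years)))
  dates <- year_dates(years, calendar)
  dates <- dates[date_year(dates) %in% years]
  yr <- date_year(dates)

  # Day-of-year phase within each year's own length: the cosine sums to zero
  # exactly over every complete year, so annual means carry only mean + warming.
  doy <- as.integer(ave(seq_along(dates), yr, FUN = seq_along))
  ylen <- as.integer(ave(doy, yr, FUN = length))
  peak_doy <- vapply(seq_along(dates), function(i) 0L, integer(1))
  # peak at the 15th of the peak month
  peak_dates <- as.Date(sprintf("%d-%02d-15", yr, params$peak_month))
  peak_doy <- as.integer(peak_dates - as.Date(sprintf("%d-01-01", yr))) + 1L
  seasonal <- params$seasonal_amplitude *
    cos(2 * pi * (doy - peak_doy) / ylen)
  warming <- warming_at(params, yr)

  n <- length(dates)
  member_seeds <- vapply(seq_len(params$n_members),
                         function(m) bitwXor(as.integer(seed), m), integer(1))
  out <- vector("list", params$n_members)
  for (m in seq_len(params$n_members)) {
    noise <- if (params$noise_sd > 0) {
      with_private_seed(member_seeds[m], {
        innov_sd <- params$noise_sd * sqrt(1 - params$ar1_rho^2)
        e <- numeric(n)
        e[1] <- stats::rnorm(1, 0, params$noise_sd) # stationary start
        if (n > 1) {
          eps <- stats::rnorm(n - 1, 0, innov_sd)
          for (i in 2:n) e[i] <- params$ar1_rho * e[i - 1] + eps[i - 1]
        }
        e
      })
    } else numeric(n)
    out[[m]] <- data.frame(
      date = dates, scenario = params$scenario_name,
      member = sprintf("m%02d", m),
      sst_c = params$mean_sst + seasonal + warming + noise
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "member_seeds") <- member_seeds
  res
}

#' Generate a synthetic 30-minute temperature-logger series
#'
#' Emulates a high-frequency water-temperature logger: 48 readings per day at
#' 30-minute cadence, equal to the day's mean temperature plus a diel cosine
#' peaking mid-afternoon (15:00) plus iid Gaussian noise. The diel cosine
#' averages to zero exactly over the 48 readings, so each day's mean reading
#' equals the input daily mean up to noise.
#'
#' @param daily_mean_curve Data.frame with columns `date` and a daily mean
#'   temperature (`sst_c` or second column).
#' @param diel_amplitude Diel half-range in degC (>= 0).
#' @param noise_sd Reading noise SD in degC (>= 0).
#' @param seed Integer seed.
#' @return Data.frame with columns `timestamp` (POSIXct, UTC) and `temp_c`.
#' @export
generate_high_frequency_series <- function(daily_mean_curve, diel_amplitude,
                                           noise_sd, seed) {
  if (diel_amplitude < 0) stop("diel_amplitude must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot("date" %in% names(daily_mean_curve))
  mean_col <- if ("sst_c" %in% names(daily_mean_curve)) "sst_c" else
    names(daily_mean_curve)[2]
  dates <- as.Date(daily_mean_curve$date)
  means <- daily_mean_curve[[mean_col]]
  stopifnot(all(is.finite(means)))

  halfhours <- seq(0, 47) # 48 readings per day
  hour <- halfhours / 2
  diel <- diel_amplitude * cos(2 * pi * (hour - 15) / 24)
  n_days <- length(dates)
  ts <- rep(as.POSIXct(paste(dates, "00:00:00"), tz = "UTC"), each = 48) +
    rep(halfhours * 1800, times = n_days)
  temp <- rep(means, each = 48) + rep(diel, times = n_days)
  if (noise_sd > 0) {
    temp <- temp + with_private_seed(seed, stats::rnorm(length(temp), 0, noise_sd))
  }
  data.frame(timestamp = ts, temp_c = temp)
}

#' Average daily SST across ensemble members
#'
#' Per-date arithmetic mean of a set of member series; the result is labelled
#' with a designated ensemble member id.
#'
#' @param members Data.frame as returned by [generate_daily_sst()] (one or more
#'   members), or a list of such data.frames.
#' @param label Member id for the averaged series.
#' @return Data.frame `date`, `scenario`, `member`, `sst_c` with one row per
#'   date.
#' @export
ensemble_mean <- function(members, label = "ensemble") {
  if (is.list(members) && !is.data.frame(members)) {
    members <- do.call(rbind, members)
  }
  stopifnot(all(c("date", "member", "sst_c") %in% names(members)))
  ids <- unique(members$member)
  date_sets <- split(members$date, members$member)
  ref <- sort(unique(as.integer(date_sets[[1]])))
  for (id in ids) {
    if (!identical(sort(unique(as.integer(date_sets[[id]]))), ref)) {
      stop("members do not cover identical dates", call. = FALSE)
    }
  }
  agg <- stats::aggregate(sst_c ~ date, data = members, FUN = mean)
  agg <- agg[order(agg$date), ]
  data.frame(date = agg$date,
             scenario = members$scenario[1],
             member = label,
             sst_c = agg$sst_c)
}

#' Built-in SSP scenario presets
#'
#' Four qualitative warming trajectories for the Gladstone climatology,
#' expressed as piecewise-linear paths of degC added to the historical
#' climatology. SSP1-1.9 overshoots its warming target mid-century and then
#' declines; SSP5-8.5 warms steeply and monotonically. Slopes are package
#' configuration, not climate-model output.
#'
#' @param ar1_rho,noise_sd,n_members Passed to [scenario_params()].
#' @return Named list of `scenario_params`, one per SSP.
#' @export
ssp_presets <- function(ar1_rho = 0.8, noise_sd = 0.5, n_members = 5L) {
  knots <- list(
    "SSP1-1.9" = data.frame(year = c(2015, 2022, 2045, 2060, 2100),
                            delta_t = c(0, 0.15, 1.1, 1.6, 1.1)),
    "SSP1-2.6" = data.frame(year = c(2015, 2022, 2050, 2100),
                            delta_t = c(0, 0.15, 1.0, 1.4)),
    "SSP3-7.0" = data.frame(year = c(2015, 2022, 2050, 2100),
                            delta_t = c(0, 0.15, 1.2, 2.6)),
    "SSP5-8.5" = data.frame(year = c(2015, 2022, 2050, 2100),
                            delta_t = c(0, 0.15, 1.5, 3.2))
  )
  out <- lapply(names(knots), function(nm) {
    gladstone_params(scenario_name = nm, warming_knots = knots[[nm]],
                     ar1_rho = ar1_rho, noise_sd = noise_sd,
                     n_members = n_members)
  })
  names(out) <- names(knots)
  out
}

#' Write / read the daily-SST CSV interchange format
#'
#' Columns `date,scenario,member,sst_c` with ISO-8601 dates.
#' @param x Daily SST data.frame.
#' @param path File path.
#' @return `read_daily_sst_csv` returns the parsed data.frame.
#' @export
write_daily_sst_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_daily_sst_csv
#' @export
read_daily_sst_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$date <- as.Date(x$date)
  x
}
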