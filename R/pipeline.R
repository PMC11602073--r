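#' Converged baseline-year cycle
#'
#' Runs the DBN under the baseline year's monthly climate probabilities,
#' repeated year after year, with *expected* (soft) evidence: each month the
#' temperature node is given the distribution `(1 - p_t^T, p_t^T)` and the
#' heat-stress node `(1 - p_t^Z, p_t^Z)`. Iteration stops when the
#' month-of-year interface joints change by less than `tol` between
#' successive years; the converged 12-month cycle of marginals is the
#' baseline reference `p_S^B`. Soft evidence makes the baseline deterministic
#' — the reference denominator of the resilience ratios carries no Monte
#' Carlo noise.
#'
#' @param dbn A [dbn_spec()] or [compile_dbn()] result.
#' @param baseline_probs Data.frame of 12 rows (months 1-12) with
#'   `p_suboptimal` and `p_heatstress`.
#' @param initial Starting interface distribution (default uniform).
#' @param tol Sup-norm convergence tolerance on the interface joints.
#' @param max_years Iteration cap; non-convergence raises an error reporting
#'   the final residual.
#' @param temp_node,heat_node Evidence node names.
#' @return A `state_trajectory` of the converged cycle with `month` 1-12 (and
#'   `year` NA), interface attributes attached.
#' @export
run_baseline <- function(dbn, baseline_probs, initial = NULL, tol = 1e-8,
                         max_years = 200, temp_node = "temperature",
                         heat_node = "heat_stress") {
  cd <- if (inherits(dbn, "compiled_dbn")) dbn else compile_dbn(dbn)
  bp <- baseline_probs[order(baseline_probs$month), ]
  if (!identical(as.integer(bp$month), 1:12)) {
    stop("baseline_probs must hold exactly months 1..12", call. = FALSE)
  }
  soft <- lapply(1:12, function(m) {
    stats::setNames(list(
      c(1 - bp$p_suboptimal[m], bp$p_suboptimal[m]),
      c(1 - bp$p_heatstress[m], bp$p_heatstress[m])
    ), c(temp_node, heat_node))
  })
  f <- resolve_initial(cd, initial)
  prev_cycle <- NULL
  resid <- Inf
  for (yr in seq_len(max_years)) {
    traj <- forward_infer(cd, soft, initial = f)
    joints <- attr(traj, "interface_joint")
    if (!is.null(prev_cycle)) {
      resid <- max(abs(joints - prev_cycle))
      if (resid < tol) {
        traj$month <- traj$slice
        traj$year <- NA_integer_
        attr(traj, "baseline_residual") <- resid
        attr(traj, "baseline_years") <- yr
        return(traj)
      }
    }
    prev_cycle <- joints
    f <- as.numeric(joints[12, ])
  }
  stop(sprintf("baseline did not converge within %d years (residual %.3g)",
               max_years, resid), call. = FALSE)
}

#' Monte Carlo scenario run
#'
#' Draws `n_samples` monthly evidence sequences from the scenario's climate
#' probabilities, filters the DBN exactly for each, drops the burn-in months,
#' and returns per-sample monthly and annual shoot-density ratios against the
#' baseline cycle. Sample `i` uses the substream seed
#' `bitwXor(seed, scenario_index * 4096 + i)` so runs are reproducible and
#' scenarios decorrelated.
#'
#' @param dbn A [dbn_spec()] or [compile_dbn()] result.
#' @param probs Monthly probabilities spanning burn-in plus horizon
#'   (contiguous whole months).
#' @param baseline_cycle Output of [run_baseline()].
#' @param n_samples Number of Monte Carlo samples (study default 100).
#' @param seed Integer study seed.
#' @param burn_in_months Leading slices discarded before metrics (default 24,
#'   the two-year initialization phase).
#' @param node Node whose state ratios are computed.
#' @param scenario_index Integer offset for substream seeding.
#' @param couple_heat_to_temp Passed to [sample_evidence()].
#' @return Object of class `scenario_ratios`: list with `monthly` and
#'   `annual` data.frames (columns `sample`, `year`, `month`, `state`,
#'   `ratio`), plus `sample_seeds`.
#' @export
run_scenario <- function(dbn, probs, baseline_cycle, n_samples = 100, seed,
                         burn_in_months = 24, node = "shoot_density",
                         scenario_index = 0L, couple_heat_to_temp = FALSE) {
  cd <- if (inherits(dbn, "compiled_dbn")) dbn else compile_dbn(dbn)
  if (nrow(probs) <= burn_in_months) {
    stop("probability sequence shorter than burn-in + horizon", call. = FALSE)
  }
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  states <- cd$dbn$nodes[[node]]$states
  keep <- (burn_in_months + 1):nrow(probs)
  bl <- baseline_cycle[baseline_cycle$node == node, ]
  pb <- matrix(NA_real_, 12, length(states), dimnames = list(NULL, states))
  for (s in states) pb[bl$month[bl$state == s], s] <-
    bl$probability[bl$state == s]
  if (anyNA(pb)) stop("baseline cycle incomplete for node states", call. = FALSE)

  month_idx <- probs$month[keep]
  year_idx <- probs$year[keep]
  sample_seeds <- vapply(seq_len(n_samples), function(i) {
    bitwXor(as.integer(seed), as.integer(scenario_index) * 4096L + i)
  }, integer(1))

  monthly <- vector("list", n_samples)
  annual <- vector("list", n_samples)
  years <- sort(unique(year_idx))
  for (i in seq_len(n_samples)) {
    evid <- sample_evidence(probs, seed = sample_seeds[i],
                            couple_heat_to_temp = couple_heat_to_temp)
    traj <- forward_infer(cd, evid, keep_nodes = node)
    pm <- matrix(traj$probability, ncol = length(states))  # slices x states
    colnames(pm) <- states
    pm <- pm[keep, , drop = FALSE]
    denom <- pb[month_idx, , drop = FALSE]
    rt <- pm / denom
    rt[denom == 0] <- NA_real_
    monthly[[i]] <- data.frame(
      sample = i, year = rep(year_idx, times = length(states)),
      month = rep(month_idx, times = length(states)),
      state = rep(states, each = length(keep)),
      ratio = as.numeric(rt))
    ann <- do.call(rbind, lapply(states, function(s) {
      v <- tapply(rt[, s], year_idx, function(x) {
        if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
      })
      data.frame(sample = i, year = years, state = s,
                 ratio = as.numeric(v[as.character(years)]))
    }))
    annual[[i]] <- ann
  }
  structure(list(
    monthly = do.call(rbind, monthly),
    annual = do.call(rbind, annual),
    node = node, states = states, sample_seeds = sample_seeds
  ), class = "scenario_ratios")
}

#' @export
print.scenario_ratios <- function(x, ...) {
  cat(sprintf("Scenario ratios: node '%s', %d sample(s), years %d-%d\n",
              x$node, max(x$annual$sample), min(x$annual$year),
              max(x$annual$year)))
  invisible(x)
}

# -- study configuration ------------------------------------------------------

#' Default study configuration
#'
#' The full study setup as a nested list with sections `climate`, `thermal`,
#' `dbn`, `study` and `metrics`. Defaults reproduce the study conditions:
#' four SSP scenarios, 100 Monte Carlo samples, 2022 baseline year, 24-month
#' burn-in, 2030-2099 horizon, thresholds 24 / 30 degC, 15-day saturation,
#' 0.9 recovery threshold and 5-year loss limit.
#'
#' @return A nested list.
#' @export
default_study_config <- function() {
  list(
    climate = list(
      mean_sst = 24.4, seasonal_amplitude = 5.25, peak_month = 1L,
      ar1_rho = 0.8, noise_sd = 0.5, n_members = 5L,
      calendar = "gregorian",
      scenarios = lapply(ssp_presets(), function(p) {
        list(warming_knots = p$warming_knots)
      })
    ),
    thermal = list(
      optimal_threshold_c = 24, mortality_threshold_c = 30,
      heatstress_saturation_days = 15,
      diel_amplitude_c = 0.6, hf_noise_sd_c = 0.25,
      fit_years = c(2016L, 2022L)
    ),
    dbn = list(spec = "default"),
    study = list(
      scenarios = names(ssp_presets()),
      n_samples = 100L, seed = 20L, baseline_year = 2022L,
      burn_in_months = 24L, horizon = c(2030L, 2099L)
    ),
    metrics = list(
      node = "shoot_density",
      recovery_threshold = 0.9, loss_limit_years = 5L,
      recovery_states = c("high", "moderate")
    )
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.data.frame(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read and validate a study configuration
#'
#' Reads a YAML study configuration and merges it over
#' [default_study_config()]; omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_study_config <- function(path) {
  doc <- yaml::read_yaml(path)
  cfg <- merge_config(default_study_config(), doc)
  validate_study_config(cfg)
  cfg
}

#' @rdname read_study_config
#' @param config Configuration list.
#' @export
validate_study_config <- function(config) {
  st <- config$study
  if (is.null(st$n_samples) || st$n_samples < 1) {
    stop("study.n_samples must be >= 1", call. = FALSE)
  }
  if (st$burn_in_months < 0) stop("study.burn_in_months must be >= 0",
                                  call. = FALSE)
  horizon <- as.integer(unlist(st$horizon))
  if (length(horizon) != 2 || horizon[2] < horizon[1]) {
    stop("study.horizon must be a non-empty year range", call. = FALSE)
  }
  known <- names(config$climate$scenarios)
  unknown <- setdiff(unlist(st$scenarios), known)
  if (length(unknown)) {
    stop(sprintf("unknown scenario(s): %s (configured: %s)",
                 paste(unknown, collapse = ", "),
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  invisible(config)
}

config_scenario_params <- function(config, scenario_name) {
  cl <- config$climate
  sc <- cl$scenarios[[scenario_name]]
  kn <- sc$warming_knots
  if (!is.data.frame(kn)) {
    kn <- as.data.frame(do.call(rbind, lapply(kn, unlist)))
    names(kn) <- c("year", "delta_t")
  }
  scenario_params(scenario_name, mean_sst = cl$mean_sst,
                  seasonal_amplitude = cl$seasonal_amplitude,
                  peak_month = cl$peak_month, warming_knots = kn,
                  ar1_rho = cl$ar1_rho, noise_sd = cl$noise_sd,
                  n_members = cl$n_members)
}

# -- full study ---------------------------------------------------------------

#' Run the full projection study
#'
#' End-to-end pipeline: (1) generate the historical synthetic climate and a
#' 30-minute logger series, (2) fit the thermal-optimality and daily-maximum
#' models, (3) project monthly evidence probabilities for the baseline year
#' and run the deterministic baseline cycle, (4) for each scenario, generate
#' the projection ensemble, project probabilities, and run the Monte Carlo
#' scenario simulation, (5) compute ratios, prediction intervals, recovery
#' metrics and permanent-loss flags, and (6) write the CSV outputs and a JSON
#' manifest to `out_dir`.
#'
#' @param config Configuration list ([default_study_config()] shape) or a
#'   path to a YAML file for [read_study_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param quiet Suppress per-stage progress messages.
#' @return Object of class `seagrass_study` with components `config`,
#'   `thermal` (fitted models), `baseline` (probabilities and cycle),
#'   `scenarios` (per-scenario ratios, summaries, recovery tables) and
#'   `manifest`.
#' @export
run_study <- function(config = default_study_config(), out_dir = NULL,
                      quiet = FALSE) {
  if (is.character(config)) config <- read_study_config(config)
  validate_study_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  st <- config$study
  th <- config$thermal
  me <- config$metrics
  horizon <- as.integer(unlist(st$horizon))
  seed <- as.integer(st$seed)

  dbn <- if (identical(config$dbn$spec, "default")) default_seagrass_dbn()
         else read_dbn_spec(config$dbn$spec)
  cd <- compile_dbn(dbn)

  # 1. historical climate + logger series
  fit_years <- as.integer(unlist(th$fit_years))
  hist_params <- config_scenario_params(config, names(config$climate$scenarios)[1])
  hist_params$scenario_name <- "historical"
  hist_params$warming_knots <- data.frame(year = c(2015, 2100), delta_t = c(0, 0))
  hist_sst <- generate_daily_sst(hist_params, fit_years[1]:fit_years[2],
                                 seed = bitwXor(seed, 101L),
                                 calendar = config$climate$calendar)
  hist_mean <- ensemble_mean(hist_sst)
  hf <- generate_high_frequency_series(hist_mean, th$diel_amplitude_c,
                                       th$hf_noise_sd_c,
                                       seed = bitwXor(seed, 202L))
  say("fitted-period climate: %d days x %d members, %d logger readings",
      nrow(hist_mean), hist_params$n_members, nrow(hf))

  # 2. thermal models
  labels <- label_daily_optimality(hf, th$optimal_threshold_c)
  maxima <- daily_maxima(hf, th$mortality_threshold_c)
  opt_model <- fit_optimality_model(labels, hist_mean, th$optimal_threshold_c)
  max_model <- fit_max_temp_model(maxima, hist_mean)
  say("thermal fits: McFadden R2 %.3f, linear R2 %.4f",
      opt_model$mcfadden_r2, max_model$r2)

  # 3. baseline
  base_sst <- hist_mean[date_year(hist_mean$date) == st$baseline_year, ]
  baseline_probs <- project_monthly_probabilities(
    opt_model, max_model, base_sst,
    mortality_threshold = th$mortality_threshold_c,
    saturation_days = th$heatstress_saturation_days)
  baseline_cycle <- run_baseline(cd, baseline_probs)
  say("baseline cycle converged in %d year(s), residual %.2g",
      attr(baseline_cycle, "baseline_years"),
      attr(baseline_cycle, "baseline_residual"))

  # 4-5. scenarios
  burn_years <- ceiling(st$burn_in_months / 12)
  proj_years <- (horizon[1] - burn_years):horizon[2]
  scen_names <- unlist(st$scenarios)
  scenarios <- list()
  for (k in seq_along(scen_names)) {
    nm <- scen_names[k]
    params <- config_scenario_params(config, nm)
    proj <- generate_daily_sst(params, proj_years,
                               seed = bitwXor(seed, 1000L + k),
                               calendar = config$climate$calendar)
    proj_mean <- ensemble_mean(proj)
    probs <- project_monthly_probabilities(
      opt_model, max_model, proj_mean,
      mortality_threshold = th$mortality_threshold_c,
      saturation_days = th$heatstress_saturation_days)
    extra <- burn_years * 12L - st$burn_in_months
    if (extra > 0) probs <- probs[-seq_len(extra), ]  # align burn-in exactly
    ratios <- run_scenario(cd, probs, baseline_cycle,
                           n_samples = st$n_samples, seed = seed,
                           burn_in_months = st$burn_in_months,
                           node = me$node, scenario_index = k)
    summaries <- lapply(ratios$states, function(s) {
      prediction_intervals(ratios$annual[ratios$annual$state == s, ])
    })
    names(summaries) <- ratios$states
    # mean annual ratio across samples drives the recovery metrics
    mean_annual <- lapply(ratios$states, function(s) {
      data.frame(year = summaries[[s]]$year, ratio = summaries[[s]]$mean)
    })
    names(mean_annual) <- ratios$states
    rec_states <- intersect(unlist(me$recovery_states), ratios$states)
    recovery <- lapply(rec_states, function(s) {
      events <- recovery_times(mean_annual[[s]], me$recovery_threshold)
      summ <- interevent_summary(mean_annual[[s]], me$recovery_threshold,
                                 period = horizon)
      list(events = events, summary = summ,
           permanent_loss = flag_permanent_loss(summ, me$loss_limit_years))
    })
    names(recovery) <- rec_states
    scenarios[[nm]] <- list(probs = probs, ratios = ratios,
                            summaries = summaries, recovery = recovery)
    say("scenario %s: %d samples x %d months done", nm, st$n_samples,
        nrow(probs) - st$burn_in_months)
  }

  study <- structure(list(
    config = config,
    thermal = list(optimality = opt_model, max_temp = max_model),
    baseline = list(probs = baseline_probs, cycle = baseline_cycle),
    scenarios = scenarios,
    manifest = NULL
  ), class = "seagrass_study")

  if (!is.null(out_dir)) {
    study$manifest <- write_study_outputs(study, out_dir)
  }
  study
}

#' Write the study's CSV outputs and manifest
#'
#' Emits `ratios_monthly.csv`, `ratios_annual.csv`, `summary.csv`,
#' `recovery_events.csv`, `recovery_summary.csv`, `baseline_cycle.csv`,
#' per-scenario monthly probability files, `manifest.json` and `run_log.txt`.
#'
#' @param study A `seagrass_study`.
#' @param out_dir Output directory.
#' @return The manifest list, invisibly stored on the study by [run_study()].
#' @export
write_study_outputs <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)

  monthly <- do.call(rbind, lapply(names(study$scenarios), function(nm) {
    x <- study$scenarios[[nm]]$ratios$monthly
    cbind(sample = x$sample, scenario = nm,
          x[, c("state", "year", "month", "ratio")])
  }))
  annual <- do.call(rbind, lapply(names(study$scenarios), function(nm) {
    x <- study$scenarios[[nm]]$ratios$annual
    cbind(sample = x$sample, scenario = nm,
          x[, c("state", "year", "ratio")])
  }))
  summaries <- do.call(rbind, lapply(names(study$scenarios), function(nm) {
    do.call(rbind, lapply(names(study$scenarios[[nm]]$summaries), function(s) {
      x <- study$scenarios[[nm]]$summaries[[s]]
      cbind(scenario = nm, state = s, as.data.frame(x))
    }))
  }))
  events <- do.call(rbind, lapply(names(study$scenarios), function(nm) {
    do.call(rbind, lapply(names(study$scenarios[[nm]]$recovery), function(s) {
      ev <- study$scenarios[[nm]]$recovery[[s]]$events
      if (!nrow(ev)) return(NULL)
      cbind(scenario = nm, state = s, ev)
    }))
  }))
  if (is.null(events)) {
    events <- data.frame(scenario = character(0), state = character(0),
                         y = integer(0), y_prime = integer(0), q = integer(0),
                         threshold = numeric(0), censored = logical(0))
  }
  recsum <- do.call(rbind, lapply(names(study$scenarios), function(nm) {
    do.call(rbind, lapply(names(study$scenarios[[nm]]$recovery), function(s) {
      r <- study$scenarios[[nm]]$recovery[[s]]
      data.frame(scenario = nm, state = s,
                 mean_recovery_years = r$summary$mean_recovery,
                 max_gap_years = r$summary$max_gap,
                 n_recovery_instances = r$summary$n_instances,
                 trailing_gap_years = r$summary$trailing_gap,
                 permanent_loss = r$permanent_loss)
    }))
  }))

  files <- list(
    ratios_monthly = monthly, ratios_annual = annual, summary = summaries,
    recovery_events = events, recovery_summary = recsum,
    baseline_cycle = as.data.frame(study$baseline$cycle)
  )
  manifest <- list(
    package = "seagrassDBN",
    seed = cfg$study$seed,
    n_samples = cfg$study$n_samples,
    scenarios = as.list(names(study$scenarios)),
    thresholds = list(
      optimal_c = cfg$thermal$optimal_threshold_c,
      mortality_c = cfg$thermal$mortality_threshold_c,
      saturation_days = cfg$thermal$heatstress_saturation_days,
      recovery = cfg$metrics$recovery_threshold,
      loss_limit_years = cfg$metrics$loss_limit_years
    ),
    conventions = list(
      percentile = "linear interpolation (quantile type 7)",
      baseline_evidence = "expected (soft)",
      annual_ratio = "mean of per-sample monthly ratios"
    ),
    files = list()
  )
  for (nm in names(files)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(files[[nm]], path, row.names = FALSE)
    manifest$files[[paste0(nm, ".csv")]] <- list(rows = nrow(files[[nm]]))
  }
  for (nm in names(study$scenarios)) {
    fn <- paste0("monthly_probabilities_", gsub("[^A-Za-z0-9.-]", "_", nm), ".csv")
    utils::write.csv(study$scenarios[[nm]]$probs, file.path(out_dir, fn),
                     row.names = FALSE)
    manifest$files[[fn]] <- list(rows = nrow(study$scenarios[[nm]]$probs))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_lines <- c(
    sprintf("seed=%d n_samples=%d burn_in_months=%d", cfg$study$seed,
            cfg$study$n_samples, cfg$study$burn_in_months),
    sprintf("thermal: mcfadden_r2=%.6f linear_r2=%.6f residual_sd=%.4f",
            study$thermal$optimality$mcfadden_r2, study$thermal$max_temp$r2,
            study$thermal$max_temp$residual_sd),
    sprintf("baseline: converged_years=%d residual=%.3g",
            attr(study$baseline$cycle, "baseline_years"),
            attr(study$baseline$cycle, "baseline_residual")),
    vapply(names(study$scenarios), function(nm) {
      sprintf("scenario %s: months=%d", nm, nrow(study$scenarios[[nm]]$probs))
    }, character(1))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  manifest
}

#' @export
print.seagrass_study <- function(x, ...) {
  st <- x$config$study
  cat(sprintf("Seagrass projection study: %d scenario(s), n = %d, %d-%d\n",
              length(x$scenarios), st$n_samples,
              unlist(st$horizon)[1], unlist(st$horizon)[2]))
  cat(sprintf("  thermal fits: McFadden R2 %.3f, max-temp R2 %.4f\n",
              x$thermal$optimality$mcfadden_r2, x$thermal$max_temp$r2))
  for (nm in names(x$scenarios)) {
    rec <- x$scenarios[[nm]]$recovery
    hi <- rec[["high"]]
    if (!is.null(hi)) {
      cat(sprintf("  %s: high-density recovery instances %d, max gap %s, loss %s\n",
                  nm, hi$summary$n_instances,
                  ifelse(is.na(hi$summary$max_gap), "NA",
                         as.character(hi$summary$max_gap)),
                  hi$permanent_loss))
    }
  }
  invisible(x)
}

#' @export
summary.seagrass_study <- function(object, ...) {
  out <- do.call(rbind, lapply(names(object$scenarios), function(nm) {
    do.call(rbind, lapply(names(object$scenarios[[nm]]$recovery), function(s) {
      r <- object$scenarios[[nm]]$recovery[[s]]
      data.frame(scenario = nm, state = s,
                 mean_recovery_years = r$summary$mean_recovery,
                 max_gap_years = r$summary$max_gap,
                 n_recovery_instances = r$summary$n_instances,
                 permanent_loss = r$permanent_loss)
    }))
  }))
  rownames(out) <- NULL
  out
}
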