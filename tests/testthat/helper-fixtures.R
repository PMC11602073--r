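# Small fixtures shared across tests. Everything is built in code.

# Noise-free Gladstone climatology, single member
quiet_gladstone <- function() {
  gladstone_params(noise_sd = 0, ar1_rho = 0)
}

# Three-node toy DBN: evidence root A, temporal chain B, leaf C
toy_chain_dbn <- function() {
  dbn_spec(list(
    dbn_node("A", c("lo", "hi"), cpt = rbind(c(0.5, 0.5))),
    dbn_node("B", c("b1", "b2"), parents = "A", temporal_parents = "B",
             # rows: (A, B_prev) first parent fastest
             cpt = rbind(c(0.9, 0.1),    # lo, b1
                         c(0.4, 0.6),    # hi, b1
                         c(0.7, 0.3),    # lo, b2
                         c(0.2, 0.8))),  # hi, b2
    dbn_node("C", c("c1", "c2"), parents = "B",
             cpt = rbind(c(0.8, 0.2),
                         c(0.3, 0.7)))
  ), evidence_nodes = "A")
}

# Two-state Markov chain as a one-node DBN (no evidence)
markov_chain_dbn <- function(p_stay = 0.9, q_stay = 0.8) {
  dbn_spec(list(
    dbn_node("X", c("x1", "x2"), temporal_parents = "X",
             cpt = rbind(c(p_stay, 1 - p_stay),
                         c(1 - q_stay, q_stay)))
  ), evidence_nodes = character(0))
}

# Monthly probability table: seasonal sub-optimality, configurable heat stress
make_monthly_probs <- function(years, p_hs_summer = 0) {
  p_sub <- c(0.95, 0.95, 0.8, 0.5, 0.2, 0.05, 0.02, 0.02, 0.1, 0.3, 0.6, 0.9)
  p_hs <- c(p_hs_summer, p_hs_summer / 2, rep(0, 9), p_hs_summer / 2)
  data.frame(year = rep(years, each = 12), month = rep(1:12, length(years)),
             n_days = rep(days_in_month_vec(years), length.out = 12 * length(years)),
             p_suboptimal = rep(p_sub, length(years)),
             p_heatstress = rep(p_hs, length(years)))
}

days_in_month_vec <- function(years) {
  rep(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31), length(years))
}

# Hand-built thermal models with known coefficients (bypass fitting)
make_opt_model <- function(beta0, beta1, threshold = 24) {
  structure(list(coefficients = c(beta0 = beta0, beta1 = beta1),
                 optimal_threshold = threshold,
                 loglik_model = NA_real_, loglik_null = NA_real_,
                 mcfadden_r2 = NA_real_, n = 0L),
            class = "thermal_optimality_model")
}

make_max_model <- function(beta0, beta1, month_effects = rep(0, 12),
                           residual_sd = 0) {
  structure(list(coefficients = c(beta0 = beta0, beta1 = beta1),
                 month_effects = month_effects, r2 = NA_real_,
                 residual_sd = residual_sd, month_encoding = "categorical",
                 months_present = 1:12, n = 0L),
            class = "max_temp_model")
}

# Max absolute marginal difference between two trajectories
traj_max_diff <- function(a, b) {
  m <- merge(as.data.frame(a), as.data.frame(b),
             by = c("slice", "node", "state"))
  max(abs(m$probability.x - m$probability.y))
}

# Simulated logger world with known logistic/linear structure:
# daily SST over `years`, labels drawn from logistic(b0 + b1*sst),
# maxima y = a0 + a1*sst + month effect + N(0, sigma)
simulate_thermal_world <- function(years = 2019:2021, b = c(-30, 1.3),
                                   a = c(2, 1.05), month_eff = NULL,
                                   sigma = 0.1, seed = 42) {
  if (is.null(month_eff)) month_eff <- c(0, seq(0.1, 1.1, by = 0.1))
  p <- quiet_gladstone()
  p$noise_sd <- 0.6; p$ar1_rho <- 0.5
  sst <- generate_daily_sst(p, years, seed = seed)
  withr_seed <- seed + 1
  set.seed(withr_seed)
  pr <- stats::plogis(b[1] + b[2] * sst$sst_c)
  labels <- data.frame(date = sst$date,
                       suboptimal = stats::runif(nrow(sst)) < pr)
  month <- as.integer(format(sst$date, "%m"))
  maxima <- data.frame(
    date = sst$date,
    y_max = a[1] + a[2] * sst$sst_c + month_eff[month] +
      stats::rnorm(nrow(sst), 0, sigma))
  list(sst = sst, labels = labels, maxima = maxima,
       b = b, a = a, month_eff = month_eff, sigma = sigma)
}
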