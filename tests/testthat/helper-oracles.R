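# Independent oracles, coded from closed forms / first principles and kept
# separate from the package's solution paths.

# Two-compartment IV bolus closed form: C(t) = A e^{-alpha t} + B e^{-beta t}
# with micro constants k10 = CL/V, k12 = CL2/V, k21 = CL2/V2.
biexp_iv_oracle <- function(t, dose, CL, V, CL2, V2) {
  k10 <- CL / V; k12 <- CL2 / V; k21 <- CL2 / V2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  A <- dose * (alpha - k21) / (V * (alpha - beta))
  B <- dose * (k21 - beta) / (V * (alpha - beta))
  A * exp(-alpha * t) + B * exp(-beta * t)
}

# Ordinary least squares slope/intercept by the hand formulas.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Direct term-by-term -2LL summation for the proportional error model.
neg2ll_oracle <- function(obs, pred, sigma) {
  sum(log(2 * pi * sigma^2 * pred^2) + (obs - pred)^2 / (sigma^2 * pred^2))
}

# Default schedules per route, built from the study's minute/hour lists.
iv_times <- c(0, 2/60, 5/60, 15/60, 30/60, 1, 2, 3, 4, 6, 8, 10, 24, 28,
              32, 48)

# Noise-free dataset for one subject at the route's reference parameters.
make_noisefree_subject <- function(route, params = reference_params(route),
                                   schedule = dose_schedule(0.5, route)) {
  tt <- sampling_schedule(route)
  conc <- simulate_profile(params, schedule, tt)$conc
  data.frame(subject_id = paste0(route, "-01"), route = route,
             time_h = tt, conc_ng_ml = conc,
             blq = as.integer(tt == 0), dose_mg_kg = 0.5,
             body_weight_g = 379.8)
}

# Multiplicatively perturb every free parameter of `params` by factors in
# [1/fac, fac] (log-uniform), reproducibly.
perturb_start <- function(params, fac = 2, seed = 42) {
  nm <- free_param_names(params$route)
  v <- ehrpk:::.params_to_vector(params, nm)
  set.seed(seed)
  f <- exp(runif(length(v), -log(fac), log(fac)))
  ehrpk:::.set_params(params, as.list(setNames(v * f, nm)))
}

free_values <- function(params) {
  ehrpk:::.params_to_vector(params, free_param_names(params$route))
}
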