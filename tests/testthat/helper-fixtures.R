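# Small fixtures built in code.

make_history <- function(obs, years = NULL, route_id = "r1") {
  obs <- as.matrix(obs)
  detection_history(route_id, years %||% (2000L + seq_len(nrow(obs))), obs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random tiny instance for the enumeration property tests.
random_instance <- function(S = sample(1:4, 1), T = sample(1:3, 1)) {
  obs <- matrix(sample(c(0L, 1L, NA_integer_), T * S, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)), T, S)
  list(obs = obs,
       psi = runif(1), th0 = runif(1), th = runif(1), thp = runif(1),
       gamma = runif(max(T - 1, 0)), eps = runif(max(T - 1, 0)),
       p1 = matrix(runif(T * S), T, S), p2 = matrix(runif(T * S), T, S),
       pi_mix = runif(1))
}

inst_route_likelihood <- function(inst) {
  h <- make_history(inst$obs)
  route_likelihood(h, list(psi = inst$psi, theta0 = inst$th0,
                           theta = inst$th, theta_prime = inst$thp,
                           gamma = inst$gamma, epsilon = inst$eps,
                           p1 = inst$p1, p2 = inst$p2,
                           pi_mix = inst$pi_mix))
}

inst_enum_likelihood <- function(inst) {
  enum_route_likelihood(inst$obs, inst$psi, inst$th0, inst$th, inst$thp,
                        inst$gamma, inst$eps, inst$p1, inst$p2, inst$pi_mix)
}

# Covariate table with no covariate columns (for intercept-only specs).
null_covariates <- function(data) {
  expand.grid(route_id = data$route_ids, year = data$years,
              stringsAsFactors = FALSE)
}

# Constant-temperature hourly series covering one non-leap breeding cycle
# (June 2013 - May 2014).
constant_cycle_hourly <- function(temp) {
  dates <- seq(as.Date("2013-06-01"), as.Date("2014-05-31"), by = "day")
  data.frame(date = rep(dates, each = 24L),
             hour = rep(0:23, times = length(dates)),
             temp_c = temp)
}
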