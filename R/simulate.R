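#' Simulation design for BBS-like synthetic data
#'
#' Bundles the true model structure, true coefficients (log-odds scale),
#' covariate-generation settings, and missingness rates that define a
#' synthetic world.  Defaults mirror a desk-scale reduction of a BBS-style
#' study (300 routes x 10 years x 20 stops) with vital-rate and detection
#' magnitudes in the range reported for widespread eastern forest
#' passerines: high initial occupancy (~0.9), moderate colonization
#' (~0.18), low extinction (~0.02), a low- and a high-detection route
#' class, a habitat fraction declining about half a percentage point over
#' 16 years, slowly rising heat-stress hours and falling cold-stress hours
#' on a latitudinal gradient.
#'
#' @param n_routes,n_years,n_stops dimensions of the synthetic survey.
#' @param spec true [model_spec()]; default: intercepts everywhere plus a
#'   habitat effect on initial occupancy and a cold-mean effect on
#'   colonization.
#' @param beta named true coefficient vector matching `spec` (names as in
#'   [fit_occu()] estimates); missing entries default to 0 and intercept
#'   defaults below.
#' @param habitat_base,habitat_gradient,habitat_trend,habitat_noise_sd
#'   habitat fraction: logit-scale base and spatial gradient, per-year
#'   linear trend (fraction/year) and noise sd on the fraction scale.
#' @param cold_base,cold_gradient,cold_trend,cold_noise_sd cold-stress
#'   hours per year: base, spatial gradient amplitude, per-year trend,
#'   noise sd.
#' @param heat_base,heat_gradient,heat_trend,heat_noise_sd heat-stress
#'   hours per year.
#' @param missing_year_rate probability a route-year is entirely
#'   unsurveyed.
#' @param missing_stop_rate probability an individual stop is unsurveyed.
#' @param seed integer seed; fully determines the generated world.
#' @return object of class `sim_design`.
#' @export
simulation_design <- function(n_routes = 300L, n_years = 10L, n_stops = 20L,
                              spec = NULL, beta = NULL,
                              habitat_base = 0.42, habitat_gradient = 0.8,
                              habitat_trend = -0.005 / 15,
                              habitat_noise_sd = 0.01,
                              cold_base = 5400, cold_gradient = 1200,
                              cold_trend = -10, cold_noise_sd = 50,
                              heat_base = 1.0, heat_gradient = 2.0,
                              heat_trend = 0.08, heat_noise_sd = 0.3,
                              missing_year_rate = 0.05,
                              missing_stop_rate = 0.02,
                              seed = 1L) {
  spec <- spec %||% model_spec(
    psi = list(t_intercept(), t_cov("habitat", "mean")),
    gamma = list(t_intercept(), t_cov("cold", "mean")))
  defaults <- c("psi:intercept" = 2.2, "theta:intercept" = -1.6,
                "theta_prime:intercept" = 1.4,
                "gamma:intercept" = qlogis(0.18),
                "epsilon:intercept" = qlogis(0.03),
                "p1:intercept" = qlogis(0.13), "p2:intercept" = qlogis(0.38),
                "pi_mix:intercept" = 0.533,
                "psi:habitat_mean" = 0.6, "gamma:cold_mean" = 0.4)
  nm <- coef_names(spec)
  full <- stats::setNames(numeric(length(nm)), nm)
  full[intersect(nm, names(defaults))] <-
    defaults[intersect(nm, names(defaults))]
  if (!is.null(beta)) {
    if (is.null(names(beta)) && length(beta) == length(nm)) {
      names(beta) <- nm
    }
    unknown <- setdiff(names(beta), nm)
    if (length(unknown)) {
      stop("beta names not in spec: ", paste(unknown, collapse = ", "))
    }
    full[names(beta)] <- beta
  }
  structure(list(n_routes = as.integer(n_routes),
                 n_years = as.integer(n_years),
                 n_stops = as.integer(n_stops),
                 spec = spec, beta = full,
                 habitat_base = habitat_base,
                 habitat_gradient = habitat_gradient,
                 habitat_trend = habitat_trend,
                 habitat_noise_sd = habitat_noise_sd,
                 cold_base = cold_base, cold_gradient = cold_gradient,
                 cold_trend = cold_trend, cold_noise_sd = cold_noise_sd,
                 heat_base = heat_base, heat_gradient = heat_gradient,
                 heat_trend = heat_trend, heat_noise_sd = heat_noise_sd,
                 missing_year_rate = missing_year_rate,
                 missing_stop_rate = missing_stop_rate,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Generate a synthetic route-by-year covariate landscape
#'
#' Routes get a latitude index `u` in `[0, 1]`; cold-stress hours increase
#' and heat-stress hours decrease with `u`, habitat fraction varies
#' smoothly with `u`, and each covariate carries a small linear temporal
#' trend plus white noise.  Raw values only; run [prepare_covariates()]
#' before fitting.
#'
#' @param design a [simulation_design()].
#' @param years calendar years (default `2001 .. 2000 + n_years`).
#' @return data frame `route_id`, `year`, `lat_index`, `habitat`, `heat`,
#'   `cold`.
#' @export
generate_landscape <- function(design, years = NULL) {
  years <- years %||% (2000L + seq_len(design$n_years))
  R <- design$n_routes
  T <- length(years)
  set.seed(design$seed)
  u <- sort(runif(R))
  yc <- seq_len(T) - (T + 1) / 2 # centered year index
  grid <- expand.grid(r = seq_len(R), t = seq_len(T))
  habitat <- plogis(qlogis(design$habitat_base) +
                      design$habitat_gradient * (u[grid$r] - 0.5)) +
    design$habitat_trend * yc[grid$t] +
    rnorm(nrow(grid), 0, design$habitat_noise_sd)
  habitat <- pmin(pmax(habitat, 0), 1)
  cold <- design$cold_base + design$cold_gradient * (u[grid$r] - 0.5) +
    design$cold_trend * yc[grid$t] + rnorm(nrow(grid), 0, design$cold_noise_sd)
  heat <- pmax(design$heat_base + design$heat_gradient * (0.5 - u[grid$r]) +
                 design$heat_trend * yc[grid$t] +
                 rnorm(nrow(grid), 0, design$heat_noise_sd), 0)
  out <- data.frame(route_id = sprintf("r%04d", grid$r),
                    year = years[grid$t],
                    lat_index = u[grid$r],
                    habitat = habitat, heat = heat, cold = cold)
  out[order(out$route_id, out$year), ]
}

#' Synthetic daily temperature extremes
#'
#' Emits a daily min/max series per route whose annual cycle tracks the
#' route's latitude index, so the covariate-engineering chain (hourly
#' interpolation, stress hours, moving average) can run end to end on
#' synthetic input.  The series is seasonally sinusoidal with noise; it is
#' shaped to produce plausible cold/heat stress-hour magnitudes, not to
#' reproduce any target series exactly.
#'
#' @param design a [simulation_design()] (only the seed and gradients are
#'   used).
#' @param n_routes number of routes to emit (default 3; daily series are
#'   bulky).
#' @param dates span of days (default two full breeding cycles).
#' @return data frame `route_id`, `date`, `tmin_c`, `tmax_c`.
#' @export
generate_daily_temperature <- function(design, n_routes = 3L,
                                       dates = seq(as.Date("2000-06-01"),
                                                   as.Date("2002-05-31"),
                                                   by = "day")) {
  set.seed(design$seed + 1L)
  u <- sort(runif(n_routes))
  doy <- as.integer(format(dates, "%j"))
  rows <- lapply(seq_len(n_routes), function(r) {
    base <- 16 - 8 * (u[r] - 0.5) # cooler at high latitude index
    season <- -12 * cos(2 * pi * (doy - 196) / 365.25)
    tmean <- base + season + rnorm(length(dates), 0, 1.5)
    spread <- pmax(rnorm(length(dates), 9, 1.5), 2)
    data.frame(route_id = sprintf("r%04d", r), date = dates,
               tmin_c = tmean - spread / 2, tmax_c = tmean + spread / 2)
  })
  do.call(rbind, rows)
}

#' Simulate detection histories from the generative occupancy model
#'
#' Exact generative counterpart of the likelihood: one mixture class per
#' route, a first-order occupancy chain over years, a Markov availability
#' chain along stops of each occupied route-year, Bernoulli detections at
#' available stops, then year- and stop-level missingness.
#'
#' @param design a [simulation_design()].
#' @param covariates prepared covariate table; default: the design's own
#'   [generate_landscape()] passed through [prepare_covariates()].
#' @param theta0_mode,dev_year conventions, as in [fit_occu()].
#' @return list with `data` (an [occu_data()]), `covariates`, and `truth`
#'   (true coefficients, per-route parameters, latent classes and
#'   occupancy states).
#' @export
simulate_dataset <- function(design, covariates = NULL,
                             theta0_mode = "theta", dev_year = "origin") {
  if (is.null(covariates)) {
    covariates <- prepare_covariates(generate_landscape(design))
  }
  years <- sort(unique(covariates$year))
  if (length(years) != design$n_years) {
    stop("covariate table years do not match the design")
  }
  R <- design$n_routes; T <- design$n_years; S <- design$n_stops
  ids <- sprintf("r%04d", seq_len(R))
  skel <- occu_data(lapply(ids, function(id) {
    detection_history(id, years, matrix(0L, T, S))
  }))
  d <- build_designs(design$spec, skel, covariates, dev_year)
  pars <- params_from_beta(d, design$beta, theta0_mode)
  set.seed(design$seed + 2L)
  cls <- 1L + rbinom(R, 1L, 1 - pars$pi_mix) # 1 = low-detection class
  z <- matrix(0L, R, T)
  z[, 1L] <- rbinom(R, 1L, pars$psi)
  for (t in seq_len(T)[-1L]) {
    pr <- ifelse(z[, t - 1L] == 1L, 1 - pars$epsilon[, t - 1L],
                 pars$gamma[, t - 1L])
    z[, t] <- rbinom(R, 1L, pr)
  }
  histories <- vector("list", R)
  for (r in seq_len(R)) {
    obs <- matrix(0L, T, S)
    p <- if (cls[r] == 1L) pars$p1 else pars$p2
    for (t in seq_len(T)) {
      if (z[r, t] == 1L) {
        a <- integer(S)
        a[1L] <- rbinom(1L, 1L, pars$theta0[r])
        for (s in seq_len(S)[-1L]) {
          a[s] <- rbinom(1L, 1L, if (a[s - 1L] == 1L)
            pars$theta_prime[r] else pars$theta[r])
        }
        obs[t, ] <- rbinom(S, 1L, a * p[, t])
      }
    }
    obs[runif(T) < design$missing_year_rate, ] <- NA_integer_
    obs[matrix(runif(T * S) < design$missing_stop_rate, T, S)] <- NA_integer_
    histories[[r]] <- detection_history(ids[r], years, obs)
  }
  list(data = occu_data(histories), covariates = covariates,
       truth = list(beta = design$beta, params = pars, class = cls,
                    z = z, design = design))
}
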