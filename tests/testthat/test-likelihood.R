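test_that("stop_forward matches closed forms and the enumeration oracle", {
  expect_equal(stop_forward(0L, 0.5, 0.5, 0.5, 1.0), 0.5)
  expect_equal(stop_forward(1L, 0.5, 0.5, 0.5, 0.8), 0.4)
  expect_equal(stop_forward(c(NA, NA, NA), 0.3, 0.2, 0.7, 0.5), 1.0)
  expect_equal(stop_forward(c(0L, 1L, 0L), 0.3, 0.2, 0.7, 0.5),
               enum_stop_forward(c(0L, 1L, 0L), 0.3, 0.2, 0.7, 0.5),
               tolerance = 1e-12)
  # a detection with p = 0 is impossible, not an error
  expect_equal(stop_forward(c(0L, 1L), 0.5, 0.5, 0.5, c(0, 0)), 0)
  expect_error(stop_forward(0L, 1.5, 0.5, 0.5, 0.5), "probability")
  expect_error(stop_forward(2L, 0.5, 0.5, 0.5, 0.5), "0, 1 or NA")
})

test_that("year_emission bridges the stop model and forbids false positives", {
  expect_equal(year_emission(c(0L, NA, 0L), 0, 0.3, 0.2, 0.7, 0.5), 1)
  expect_equal(year_emission(c(0L, 1L, 0L), 0, 0.3, 0.2, 0.7, 0.5), 0)
  expect_equal(year_emission(0L, 1, 0.5, 0.5, 0.5, 1.0),
               stop_forward(0L, 0.5, 0.5, 0.5, 1.0))
})

test_that("route_likelihood handles degenerate occupancy", {
  h <- make_history(rbind(c(0L, 0L), c(0L, 0L)))
  # psi = 0 with no colonization: the route is never occupied
  base <- list(psi = 0, theta = 0.3, theta_prime = 0.6, gamma = 0,
               epsilon = 0.1, p1 = 0.4, p2 = 0.7, pi_mix = 0.5)
  expect_equal(route_likelihood(h, base), 1.0)
  h2 <- make_history(rbind(c(0L, 1L), c(0L, 0L)))
  expect_equal(route_likelihood(h2, base), 0.0)
})

test_that("route_likelihood equals full latent enumeration (property)", {
  set.seed(42)
  for (i in 1:200) {
    inst <- random_instance()
    expect_equal(inst_route_likelihood(inst), inst_enum_likelihood(inst),
                 tolerance = 1e-12)
  }
})

test_that("degenerate availability chain collapses to independent stops", {
  # theta0 = theta = theta_prime = th makes availability iid Bernoulli(th),
  # so per-stop detection is independent with probability th * p
  set.seed(7)
  th <- 0.45; p <- 0.6
  for (i in 1:20) {
    T <- sample(2:3, 1); S <- sample(2:4, 1)
    obs <- matrix(sample(c(0L, 1L, NA_integer_), T * S, replace = TRUE,
                         prob = c(0.5, 0.3, 0.2)), T, S)
    psi <- runif(1); gamma <- runif(T - 1); eps <- runif(T - 1)
    lik <- route_likelihood(
      make_history(obs),
      list(psi = psi, theta0 = th, theta = th, theta_prime = th,
           gamma = gamma, epsilon = eps, p1 = p, p2 = p, pi_mix = 0.5))
    expect_equal(lik, simple_dynocc_lik(obs, psi, th * p, gamma, eps),
                 tolerance = 1e-12)
  }
})

test_that("route likelihoods are probabilities", {
  set.seed(11)
  for (i in 1:100) {
    l <- inst_route_likelihood(random_instance())
    expect_gte(l, 0); expect_lte(l, 1)
  }
})

test_that("stationary theta0 option changes only the first stop", {
  y <- c(0L, 1L, 0L)
  pars <- list(psi = 1, theta = 0.2, theta_prime = 0.7, gamma = numeric(0),
               epsilon = numeric(0), p1 = 0.5, p2 = 0.5, pi_mix = 0.5)
  h <- make_history(matrix(y, 1))
  l_theta <- route_likelihood(h, pars, theta0_mode = "theta")
  l_stat <- route_likelihood(h, pars, theta0_mode = "stationary")
  expect_equal(l_theta, enum_stop_forward(y, 0.2, 0.2, 0.7, 0.5),
               tolerance = 1e-12)
  expect_equal(l_stat,
               enum_stop_forward(y, 0.2 / (0.2 + 0.3), 0.2, 0.7, 0.5),
               tolerance = 1e-12)
})

test_that("neg2_loglik is additive over routes and permutation-invariant", {
  set.seed(5)
  des <- simulation_design(n_routes = 12, n_years = 4, n_stops = 5, seed = 5)
  sim <- simulate_dataset(des)
  spec <- model_spec()
  beta <- c(0.5, -1, 1, -1.5, -2, -1, 0.2, 0.3)
  v <- neg2_loglik(sim$data, beta, spec, sim$covariates)
  # doubling the dataset doubles -2LL
  dbl <- occu_data(c(sim$data$histories,
                     lapply(sim$data$histories, function(h) {
                       h$route_id <- paste0(h$route_id, "b"); h
                     })))
  cov2 <- rbind(sim$covariates,
                transform(sim$covariates,
                          route_id = paste0(route_id, "b")))
  expect_equal(neg2_loglik(dbl, beta, spec, cov2), 2 * v, tolerance = 1e-10)
  # permuting route order changes nothing
  perm <- occu_data(sim$data$histories[sample(12)])
  expect_equal(neg2_loglik(perm, beta, spec, sim$covariates), v,
               tolerance = 1e-10)
})

test_that("neg2_loglik matches the enumeration oracle on a tiny dataset", {
  set.seed(9)
  T <- 3; S <- 3; R <- 4
  hs <- lapply(seq_len(R), function(r) {
    make_history(matrix(sample(c(0L, 1L), T * S, TRUE), T, S),
                 route_id = paste0("r", r))
  })
  data <- occu_data(hs)
  spec <- model_spec()
  beta <- c("psi:intercept" = 0.3, "theta:intercept" = -0.5,
            "theta_prime:intercept" = 0.8, "gamma:intercept" = -0.7,
            "epsilon:intercept" = -1.1, "p1:intercept" = -0.6,
            "p2:intercept" = 0.4, "pi_mix:intercept" = 0.25)
  v <- neg2_loglik(data, beta, spec, null_covariates(data))
  th <- plogis(-0.5); thp <- plogis(0.8)
  oracle <- -2 * sum(vapply(hs, function(h) {
    log(enum_route_likelihood(
      h$obs, plogis(0.3), th, th, thp,
      rep(plogis(-0.7), T - 1), rep(plogis(-1.1), T - 1),
      matrix(plogis(-0.6), T, S), matrix(plogis(0.4), T, S),
      plogis(0.25)))
  }, 0))
  expect_equal(v, oracle, tolerance = 1e-10)
})

test_that("incompatible data yield +Inf flagged, not an error", {
  h <- make_history(rbind(c(1L, 0L)))
  data <- occu_data(list(h))
  spec <- model_spec()
  beta <- c(-800, 0, 0, -800, 0, 0, 0, 0) # psi, gamma underflow to exact 0
  v <- neg2_loglik(data, beta, spec, null_covariates(data))
  expect_true(is.infinite(v))
  expect_true(isTRUE(attr(v, "zero_likelihood")))
})

test_that("annual occupancy propagates and finds its fixed point", {
  expect_equal(annual_occupancy(0.9, 0.18, 0.02), c(0.9, 0.9))
  expect_equal(annual_occupancy(0.4, c(0, 0), c(0, 0)), rep(0.4, 3))
  expect_equal(annual_occupancy(0, 1, 0)[2], 1)
  # convergence to the equilibrium under constant rates
  traj <- annual_occupancy(0.1, rep(0.3, 60), rep(0.1, 60))
  expect_equal(traj[61], equilibrium_occupancy(0.3, 0.1), tolerance = 1e-9)
})

test_that("equilibrium occupancy closed form", {
  expect_equal(equilibrium_occupancy(0.18, 0.02), 0.9)
  expect_equal(equilibrium_occupancy(0.33, 0.33), 0.5)
  expect_equal(equilibrium_occupancy(0.49, 0.04), 0.49 / 0.53)
  expect_error(equilibrium_occupancy(0, 0), "undefined")
})

test_that("route_detection_prob complements the all-zero forward pass", {
  expect_equal(route_detection_prob(0.5, 0.2, 0.7, 0, 0, 0.5, 10), 0)
  expect_equal(route_detection_prob(0.5, 0.2, 0.7, 0.8, 0.8, 1, 1), 0.4)
  q <- enum_stop_forward(rep(0L, 4), 0.3, 0.2, 0.7, 0.5)
  expect_equal(route_detection_prob(0.3, 0.2, 0.7, 0.5, 0.5, 0.5, 4),
               1 - q, tolerance = 1e-12)
})
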