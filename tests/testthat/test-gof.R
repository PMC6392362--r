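test_that("naive transition candidates follow the detection states", {
  h1 <- make_history(rbind(c(0L, 0L), c(0L, 1L)))            # colonization
  h2 <- make_history(rbind(c(1L, 0L), c(0L, 0L)), route_id = "r2") # extinction
  h3 <- make_history(rbind(c(1L, 0L), c(NA, NA)), route_id = "r3") # unsurveyed
  ev <- naive_transition_events(occu_data(list(h1, h2, h3)))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$kind, c("colonization", "extinction"))
  expect_equal(ev$observed, c(1L, 1L))
  # no flip -> observed 0
  h4 <- make_history(rbind(c(0L, 1L), c(1L, 0L)))
  ev4 <- naive_transition_events(occu_data(list(h4)))
  expect_equal(ev4$kind, "extinction")
  expect_equal(ev4$observed, 0L)
})

test_that("expected rates collapse to the state process under perfect detection", {
  # deterministic detection: expected colonization prob equals gamma
  obs <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L))
  data <- occu_data(list(make_history(obs)))
  spec <- model_spec()
  big <- 30 # logit scale ~ certainty
  beta <- c("psi:intercept" = -big, "theta:intercept" = big,
            "theta_prime:intercept" = big, "gamma:intercept" = qlogis(0.3),
            "epsilon:intercept" = -big, "p1:intercept" = big,
            "p2:intercept" = big, "pi_mix:intercept" = 0)
  fake_fit <- structure(list(spec = spec, estimates = beta,
                             theta0_mode = "theta", dev_year = "origin"),
                        class = "occu_fit")
  ev <- expected_naive_rates(fake_fit, data, null_covariates(data))
  col <- ev[ev$kind == "colonization", ]
  expect_equal(col$expected_prob, rep(0.3, nrow(col)), tolerance = 1e-6)
  # psi = 1, epsilon = 0, perfect detection: extinction prob 0
  beta2 <- beta
  beta2[["psi:intercept"]] <- big
  obs2 <- rbind(c(1L, 1L), c(1L, 1L))
  data2 <- occu_data(list(make_history(obs2)))
  fake2 <- structure(list(spec = spec, estimates = beta2,
                          theta0_mode = "theta", dev_year = "origin"),
                     class = "occu_fit")
  ev2 <- expected_naive_rates(fake2, data2, null_covariates(data2))
  expect_equal(ev2$expected_prob[ev2$kind == "extinction"],
               rep(0, sum(ev2$kind == "extinction")), tolerance = 1e-9)
})

test_that("expected rates match the brute-force conditional probability", {
  set.seed(17)
  spec <- model_spec()
  for (i in 1:15) {
    T <- 3; S <- 3
    obs <- matrix(sample(c(0L, 1L), T * S, TRUE, prob = c(0.7, 0.3)), T, S)
    data <- occu_data(list(make_history(obs)))
    beta <- setNames(rnorm(8, 0, 1), occpart:::coef_names(spec))
    fake <- structure(list(spec = spec, estimates = beta,
                           theta0_mode = "theta", dev_year = "origin"),
                      class = "occu_fit")
    ev <- expected_naive_rates(fake, data, null_covariates(data))
    th <- plogis(beta[["theta:intercept"]])
    thp <- plogis(beta[["theta_prime:intercept"]])
    for (j in seq_len(nrow(ev))) {
      t <- match(ev$from_year[j], data$years)
      oracle <- enum_expected_flip(
        obs, t, plogis(beta[["psi:intercept"]]), th, th, thp,
        rep(plogis(beta[["gamma:intercept"]]), T - 1),
        rep(plogis(beta[["epsilon:intercept"]]), T - 1),
        matrix(plogis(beta[["p1:intercept"]]), T, S),
        matrix(plogis(beta[["p2:intercept"]]), T, S),
        plogis(beta[["pi_mix:intercept"]]))
      expect_equal(ev$expected_prob[j], unname(oracle), tolerance = 1e-9)
    }
  }
})

test_that("mixture marginalization is consistent at the extremes", {
  set.seed(18)
  obs <- matrix(sample(c(0L, 1L), 9, TRUE), 3, 3)
  data <- occu_data(list(make_history(obs)))
  spec <- model_spec()
  beta <- setNames(rnorm(8), occpart:::coef_names(spec))
  for (pi_logit in c(-30, 30)) {
    beta[["pi_mix:intercept"]] <- pi_logit
    # tie both classes to the active class: result must be identical
    active <- if (pi_logit > 0) "p1:intercept" else "p2:intercept"
    other <- setdiff(c("p1:intercept", "p2:intercept"), active)
    beta_tied <- beta
    beta_tied[[other]] <- beta[[active]]
    f1 <- structure(list(spec = spec, estimates = beta,
                         theta0_mode = "theta", dev_year = "origin"),
                    class = "occu_fit")
    f2 <- structure(list(spec = spec, estimates = beta_tied,
                         theta0_mode = "theta", dev_year = "origin"),
                    class = "occu_fit")
    e1 <- expected_naive_rates(f1, data, null_covariates(data))
    e2 <- expected_naive_rates(f2, data, null_covariates(data))
    expect_equal(e1$expected_prob, e2$expected_prob, tolerance = 1e-9)
  }
})

test_that("hosmer_lemeshow reproduces the hand-computed two-bin fixture", {
  # bin A: n=10, O=3, E=2.5; bin B: n=10, O=7, E=7.5
  events <- data.frame(
    observed = c(rep(1L, 3), rep(0L, 7), rep(1L, 7), rep(0L, 3)),
    expected_prob = c(rep(0.25, 10), rep(0.75, 10)))
  hl <- hosmer_lemeshow(events, n_bins = 2, min_expected = 0)
  chi2_hand <- 0.5^2 / 2.5 + 0.5^2 / 7.5 + 0.5^2 / 7.5 + 0.5^2 / 2.5
  expect_equal(hl$chi2, chi2_hand)
  expect_equal(hl$df, 0L)
  expect_equal(hl$bins$n, c(10L, 10L))
})

test_that("perfectly calibrated bins give chi2 = 0 exactly", {
  events <- data.frame(
    observed = c(rep(1L, 2), rep(0L, 8), rep(1L, 8), rep(0L, 2)),
    expected_prob = c(rep(0.2, 10), rep(0.8, 10)))
  hl <- hosmer_lemeshow(events, n_bins = 2, min_expected = 0)
  expect_identical(hl$chi2, 0)
})

test_that("pooling honors the minimum expected count and reduces df", {
  set.seed(19)
  p <- c(runif(80, 0.3, 0.7), runif(6, 0.0, 0.02))
  events <- data.frame(observed = rbinom(86, 1, p), expected_prob = p)
  hl <- hosmer_lemeshow(events, n_bins = 10, min_expected = 4)
  expect_true(all(hl$bins$expected > 4))
  expect_equal(hl$df, nrow(hl$bins) - 2L)
  expect_lte(hl$df, 8L)
  # invariant to event ordering
  hl2 <- hosmer_lemeshow(events[sample(86), ], n_bins = 10,
                         min_expected = 4)
  expect_equal(hl2$chi2, hl$chi2)
})
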