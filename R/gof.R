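#' Naive colonization/extinction candidate events
#'
#' A route-transition (year `t` to `t + 1`, both surveyed) is a naive
#' colonization candidate when year `t` had no detections, and a naive
#' extinction candidate when year `t` had at least one detection.  The
#' observed outcome is 1 when the detection state flips in `t + 1`.
#'
#' @param data an [occu_data()] dataset.
#' @return data frame with columns `route_id`, `from_year`, `kind`
#'   (`"colonization"` / `"extinction"`), `observed`, and a placeholder
#'   `expected_prob` column (`NA` until [expected_naive_rates()]).
#' @export
naive_transition_events <- function(data) {
  rows <- lapply(data$histories, function(h) {
    det <- apply(h$obs, 1L, function(v) any(v == 1L, na.rm = TRUE))
    surveyed <- rowSums(!is.na(h$obs)) > 0L
    T <- length(h$years)
    if (T < 2L) return(NULL)
    t <- which(surveyed[-T] & surveyed[-1L])
    if (!length(t)) return(NULL)
    data.frame(route_id = h$route_id, from_year = h$years[t],
               kind = ifelse(det[t], "extinction", "colonization"),
               observed = as.integer(det[t + 1L] != det[t]),
               expected_prob = NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model-expected naive transition rates
#'
#' Fills `expected_prob` on each candidate event with the model-implied
#' probability that the route's detection state flips at `t + 1`:
#' for a colonization candidate, `Pr(>=1 detection in t+1 | history)`; for
#' an extinction candidate, `Pr(no detection in t+1 | history)`.  The
#' conditioning history is the full observation record through year `t`
#' (forward filtering over occupancy jointly with the route-level mixture
#' class), or only year `t`'s record with `conditioning = "year_t"`.
#'
#' @param fit a converged [fit_occu()] result.
#' @param data the dataset the model was fitted to.
#' @param covariates the prepared covariate table used in fitting.
#' @param events optionally, precomputed [naive_transition_events()].
#' @param conditioning `"full_history"` (default) or `"year_t"`.
#' @return the events data frame with `expected_prob` filled.
#' @export
expected_naive_rates <- function(fit, data, covariates, events = NULL,
                                 conditioning = c("full_history", "year_t")) {
  conditioning <- match.arg(conditioning)
  events <- events %||% naive_transition_events(data)
  d <- build_designs(fit$spec, data, covariates, fit$dev_year)
  pars <- params_from_beta(d, fit$estimates, fit$theta0_mode)
  T <- d$T; S <- d$S
  y0 <- matrix(NA_integer_, S, 1L)
  y0[] <- 0L
  out <- numeric(nrow(events))
  for (r in seq_len(d$R)) {
    h <- data$histories[[r]]
    ev_idx <- which(events$route_id == h$route_id)
    if (!length(ev_idx)) next
    obs_st <- t(h$obs) # S x T
    em <- list(cpp_year_emissions(obs_st, pars$theta0[r], pars$theta[r],
                                  pars$theta_prime[r], pars$p1),
               cpp_year_emissions(obs_st, pars$theta0[r], pars$theta[r],
                                  pars$theta_prime[r], pars$p2))
    w <- c(pars$pi_mix, 1 - pars$pi_mix)
    # forward filter: f[class, state(0/1), t] joint with y_{1:t}
    f <- array(0, c(2L, 2L, T))
    for (cls in 1:2) {
      f[cls, 1L, 1L] <- w[cls] * (1 - pars$psi[r]) * em[[cls]][1L, 1L]
      f[cls, 2L, 1L] <- w[cls] * pars$psi[r] * em[[cls]][1L, 2L]
      for (t in 2:T) {
        g <- pars$gamma[r, t - 1L]; e <- pars$epsilon[r, t - 1L]
        f[cls, 1L, t] <- (f[cls, 1L, t - 1L] * (1 - g) +
                            f[cls, 2L, t - 1L] * e) * em[[cls]][t, 1L]
        f[cls, 2L, t] <- (f[cls, 1L, t - 1L] * g +
                            f[cls, 2L, t - 1L] * (1 - e)) * em[[cls]][t, 2L]
      }
    }
    for (i in ev_idx) {
      t <- match(events$from_year[i], h$years)
      post <- matrix(0, 2L, 2L) # class x state at t, given conditioning set
      if (conditioning == "full_history") {
        post[] <- f[, , t]
      } else {
        for (cls in 1:2) {
          post[cls, 1L] <- w[cls] * em[[cls]][t, 1L]
          post[cls, 2L] <- w[cls] * em[[cls]][t, 2L]
        }
      }
      tot <- sum(post)
      if (tot <= 0) stop("zero-probability history in forward filter (log-domain computation required)")
      post <- post / tot
      g <- pars$gamma[r, t]; e <- pars$epsilon[r, t]
      # detection prob in t+1 per class, given occupancy
      pd <- vapply(1:2, function(cls) {
        p_col <- if (cls == 1L) pars$p1[, t + 1L] else pars$p2[, t + 1L]
        1 - cpp_stop_forward(y0[, 1L], pars$theta0[r], pars$theta[r],
                             pars$theta_prime[r], p_col)
      }, 0)
      pr_det <- sum(vapply(1:2, function(cls) {
        pz1 <- post[cls, 1L] * g + post[cls, 2L] * (1 - e)
        pz1 * pd[cls]
      }, 0))
      out[i] <- if (events$kind[i] == "colonization") pr_det else 1 - pr_det
    }
  }
  events$expected_prob <- out
  events
}

#' Hosmer-Lemeshow calibration test on transition events
#'
#' Bins events into deciles of `expected_prob`, pools adjacent bins (from
#' the sparse end) until every bin's summed expected events exceeds
#' `min_expected`, and computes
#' `chi2 = sum[(O - E)^2 / E + ((n - O) - (n - E))^2 / (n - E)]` with
#' `df = bins - 2`.
#'
#' @param events data frame with `observed` and `expected_prob` columns
#'   (one `kind` at a time; see [naive_transition_events()]).
#' @param n_bins initial number of quantile bins.
#' @param min_expected pooling threshold on each bin's expected events.
#' @return list with `chi2`, `df`, `p`, and the bin table.
#' @export
hosmer_lemeshow <- function(events, n_bins = 10L, min_expected = 4) {
  p <- events$expected_prob
  o <- events$observed
  if (anyNA(p)) stop("expected_prob not filled; run expected_naive_rates()")
  br <- unique(quantile(p, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- cut(p, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- function(b) {
    data.frame(bin = sort(unique(b)),
               n = as.vector(table(b)),
               observed = as.vector(tapply(o, b, sum)),
               expected = as.vector(tapply(p, b, sum)))
  }
  bt <- tab(bin)
  # pool: merge the most sparse offending bin into its neighbor
  while (nrow(bt) > 2L && any(bt$expected <= min_expected)) {
    i <- which(bt$expected <= min_expected)[1L]
    j <- if (i == 1L) 2L else if (i == nrow(bt)) i - 1L else
      if (bt$expected[i - 1L] <= bt$expected[i + 1L]) i - 1L else i + 1L
    bin[bin == bt$bin[i]] <- bt$bin[j]
    bt <- tab(bin)
  }
  if (nrow(bt) < 2L) stop("fewer than 2 bins after pooling")
  with_chi <- function(O, E, n) {
    miss <- (n - O) - (n - E)
    (O - E)^2 / E + miss^2 / (n - E)
  }
  chi2 <- sum(with_chi(bt$observed, bt$expected, bt$n))
  df <- nrow(bt) - 2L
  pval <- if (df >= 1L) pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  list(chi2 = chi2, df = df, p = pval, bins = bt)
}

#' Goodness of fit on naive turnover rates
#'
#' Convenience wrapper running [naive_transition_events()],
#' [expected_naive_rates()], and [hosmer_lemeshow()] separately for
#' colonization and extinction.
#'
#' @inheritParams expected_naive_rates
#' @inheritParams hosmer_lemeshow
#' @return named list with `colonization` and `extinction` test results.
#' @export
gof_naive_rates <- function(fit, data, covariates, n_bins = 10L,
                            min_expected = 4,
                            conditioning = "full_history") {
  ev <- expected_naive_rates(fit, data, covariates,
                             conditioning = conditioning)
  lapply(stats::setNames(nm = c("colonization", "extinction")),
         function(k) {
    sub <- ev[ev$kind == k, ]
    if (!nrow(sub)) return(NULL)
    hosmer_lemeshow(sub, n_bins, min_expected)
  })
}
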