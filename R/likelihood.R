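#' Probability of a stop-level observation vector given route occupancy
#'
#' Forward pass over the two-state availability chain along the stops of a
#' route: availability at the first stop is Bernoulli(`theta0`); at later
#' stops it follows a first-order Markov chain with persistence `theta_prime`
#' (available at previous stop) and onset `theta` (unavailable at previous
#' stop).  An available stop is detected with its per-stop probability `p`,
#' an unavailable stop is never detected, and a missing stop (`NA`)
#' contributes emission 1 while the chain still advances.
#'
#' @param y integer vector of stop observations in `{0, 1, NA}`.
#' @param theta0 availability probability at the first stop.
#' @param theta,theta_prime Markov availability parameters.
#' @param p per-stop detection probability, scalar or `length(y)`.
#' @return `Pr(y | route occupied, detection class fixed)`.
#' @examples
#' stop_forward(c(0, 1, 0), 0.3, 0.2, 0.7, 0.5)
#' @export
stop_forward <- function(y, theta0, theta, theta_prime, p) {
  .assert_prob(theta0, "theta0"); .assert_prob(theta, "theta")
  .assert_prob(theta_prime, "theta_prime"); .assert_prob(p, "p")
  y <- as.integer(y)
  if (any(!(y %in% c(0L, 1L, NA_integer_)))) {
    stop("'y' entries must be 0, 1 or NA")
  }
  p <- rep_len(p, length(y))
  cpp_stop_forward(y, theta0, theta, theta_prime, p)
}

#' Year-level emission probability given occupancy state
#'
#' Bridges the stop model to the season model.  If the route is unoccupied
#' (`z = 0`), the observation probability is 1 for an all-zero/missing row
#' and 0 if any detection occurred (no false positives); if occupied it is
#' [stop_forward()].
#'
#' @inheritParams stop_forward
#' @param z occupancy state, 0 or 1.
#' @export
year_emission <- function(y, z, theta0, theta, theta_prime, p) {
  if (!z %in% c(0, 1)) stop("'z' must be 0 or 1")
  if (z == 0) {
    return(if (any(y == 1, na.rm = TRUE)) 0 else 1)
  }
  stop_forward(y, theta0, theta, theta_prime, p)
}

# Resolve the first-stop availability convention.
theta0_value <- function(theta, theta_prime, mode = c("theta", "stationary")) {
  mode <- match.arg(mode)
  if (mode == "theta") theta else theta / (theta + 1 - theta_prime)
}

#' Likelihood of one route's detection history
#'
#' Exact likelihood under the dynamic correlated-detection occupancy model
#' with a two-class detection mixture.  The mixture class is drawn once per
#' route and shared by all its years; within each class a two-state forward
#' recursion over years (initial occupancy `psi`, colonization `gamma[t]`,
#' extinction `epsilon[t]`) multiplies year-level emissions from the stop
#' model.
#'
#' @param history a [detection_history()].
#' @param params list with elements `psi`, `theta0` (optional), `theta`,
#'   `theta_prime`, `gamma`, `epsilon` (length `T - 1`), `p1`, `p2`
#'   (`T x S` matrices or scalars), `pi_mix`.
#' @param theta0_mode used when `params$theta0` is absent: `"theta"` sets
#'   the first-stop availability to `theta`; `"stationary"` to
#'   `theta / (theta + 1 - theta_prime)`.
#' @return a probability in `[0, 1]`.
#' @export
route_likelihood <- function(history, params, theta0_mode = "theta") {
  stopifnot(inherits(history, "detection_history"))
  T <- length(history$years); S <- history$n_stops
  if (T < 1L) stop("history with zero years")
  for (nm in c("psi", "theta", "theta_prime", "pi_mix")) {
    .assert_prob(params[[nm]], nm)
  }
  th0 <- params$theta0 %||%
    theta0_value(params$theta, params$theta_prime, theta0_mode)
  .assert_prob(th0, "theta0")
  gamma <- rep_len(params$gamma %||% numeric(0), max(T - 1L, 0L))
  eps <- rep_len(params$epsilon %||% numeric(0), max(T - 1L, 0L))
  if (T > 1L) { .assert_prob(gamma, "gamma"); .assert_prob(eps, "epsilon") }
  as_p <- function(p) {
    if (is.matrix(p)) {
      if (!all(dim(p) == c(T, S))) stop("p matrices must be T x S")
      t(p)
    } else matrix(rep_len(p, S * T), S, T)
  }
  p1 <- as_p(params$p1); p2 <- as_p(params$p2)
  .assert_prob(p1, "p1"); .assert_prob(p2, "p2")
  cpp_route_likelihood(t(history$obs), params$psi, th0, params$theta,
                       params$theta_prime, gamma, eps, p1, p2,
                       params$pi_mix)
}

#' Annual occupancy trajectory implied by vital rates
#'
#' Propagates occupancy through the Markov state equation
#' `psi[t+1] = psi[t] * (1 - epsilon[t]) + (1 - psi[t]) * gamma[t]`.
#'
#' @param psi1 first-season occupancy probability.
#' @param gamma,epsilon colonization/extinction series of length `T - 1`
#'   (scalars are recycled to a common length).
#' @return numeric vector of length `T` starting at `psi1`.
#' @export
annual_occupancy <- function(psi1, gamma, epsilon) {
  .assert_prob(psi1, "psi1")
  n <- max(length(gamma), length(epsilon))
  gamma <- rep_len(gamma, n); epsilon <- rep_len(epsilon, n)
  .assert_prob(gamma, "gamma"); .assert_prob(epsilon, "epsilon")
  psi <- numeric(n + 1L)
  psi[1L] <- psi1
  for (t in seq_len(n)) {
    psi[t + 1L] <- psi[t] * (1 - epsilon[t]) + (1 - psi[t]) * gamma[t]
  }
  psi
}

#' Equilibrium occupancy under constant vital rates
#'
#' The stationary point `gamma / (gamma + epsilon)` of the occupancy
#' recursion; undefined when both rates are zero.
#'
#' @param gamma colonization probability.
#' @param epsilon extinction probability.
#' @export
equilibrium_occupancy <- function(gamma, epsilon) {
  .assert_prob(gamma, "gamma"); .assert_prob(epsilon, "epsilon")
  out <- gamma / (gamma + epsilon)
  if (any(gamma + epsilon == 0)) {
    stop("equilibrium occupancy undefined when gamma = epsilon = 0")
  }
  out
}

#' Route-level detection probability
#'
#' Probability of at least one detection on an occupied route-year,
#' mixture-weighted over the two detection classes:
#' `1 - sum_c w_c * Pr(all stops zero | class c)`.
#'
#' @param theta0,theta,theta_prime availability parameters.
#' @param p1,p2 per-stop detection probabilities (scalar or length
#'   `n_stops`) for the low/high class.
#' @param pi_mix weight of class 1.
#' @param n_stops number of stops.
#' @export
route_detection_prob <- function(theta0, theta, theta_prime, p1, p2,
                                 pi_mix = 1, n_stops = 50L) {
  y0 <- integer(n_stops)
  q1 <- stop_forward(y0, theta0, theta, theta_prime, rep_len(p1, n_stops))
  q2 <- stop_forward(y0, theta0, theta, theta_prime, rep_len(p2, n_stops))
  1 - (pi_mix * q1 + (1 - pi_mix) * q2)
}
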