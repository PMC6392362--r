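# Independent brute-force oracles: full enumeration of latent availability
# and occupancy sequences.  Deliberately slow and simple; used only on
# instances with S <= 4 stops and T <= 3 years.

enum_stop_forward <- function(y, th0, th, thp, p) {
  S <- length(y)
  p <- rep_len(p, S)
  total <- 0
  for (mask in 0:(2^S - 1)) {
    a <- as.integer(intToBits(mask))[seq_len(S)]
    pr <- if (a[1L] == 1L) th0 else 1 - th0
    for (s in seq_len(S)[-1L]) {
      pr <- pr * if (a[s - 1L] == 1L) {
        if (a[s] == 1L) thp else 1 - thp
      } else {
        if (a[s] == 1L) th else 1 - th
      }
    }
    em <- 1
    for (s in seq_len(S)) {
      if (is.na(y[s])) next
      em <- em * if (a[s] == 1L) {
        if (y[s] == 1L) p[s] else 1 - p[s]
      } else {
        if (y[s] == 1L) 0 else 1
      }
    }
    total <- total + pr * em
  }
  total
}

# obs: T x S matrix; p1, p2: T x S matrices
enum_route_likelihood <- function(obs, psi, th0, th, thp, gamma, eps,
                                  p1, p2, pi_mix) {
  T <- nrow(obs)
  total <- 0
  for (cls in 1:2) {
    w <- if (cls == 1L) pi_mix else 1 - pi_mix
    p <- if (cls == 1L) p1 else p2
    for (mask in 0:(2^T - 1)) {
      z <- as.integer(intToBits(mask))[seq_len(T)]
      pr <- if (z[1L] == 1L) psi else 1 - psi
      for (t in seq_len(T)[-1L]) {
        pr <- pr * if (z[t - 1L] == 0L) {
          if (z[t] == 1L) gamma[t - 1L] else 1 - gamma[t - 1L]
        } else {
          if (z[t] == 0L) eps[t - 1L] else 1 - eps[t - 1L]
        }
      }
      em <- 1
      for (t in seq_len(T)) {
        em <- em * if (z[t] == 1L) {
          enum_stop_forward(obs[t, ], th0, th, thp, p[t, ])
        } else {
          if (any(obs[t, ] == 1L, na.rm = TRUE)) 0 else 1
        }
      }
      total <- total + w * pr * em
    }
  }
  total
}

# Standard multi-season occupancy likelihood with independent per-stop
# detection probability q (no availability chain): the degenerate-chain
# reference implementation.
simple_dynocc_lik <- function(obs, psi, q, gamma, eps) {
  T <- nrow(obs)
  emis <- function(t, z) {
    y <- obs[t, ]
    if (z == 0L) return(if (any(y == 1L, na.rm = TRUE)) 0 else 1)
    ok <- !is.na(y)
    prod(ifelse(y[ok] == 1L, q, 1 - q))
  }
  f0 <- (1 - psi) * emis(1L, 0L)
  f1 <- psi * emis(1L, 1L)
  for (t in seq_len(T)[-1L]) {
    n0 <- (f0 * (1 - gamma[t - 1L]) + f1 * eps[t - 1L]) * emis(t, 0L)
    n1 <- (f0 * gamma[t - 1L] + f1 * (1 - eps[t - 1L])) * emis(t, 1L)
    f0 <- n0; f1 <- n1
  }
  f0 + f1
}

# Brute-force conditional flip probability for the GOF expected rates:
# Pr(detection state flips at t+1 | y_{1:t}), marginalizing class and all
# occupancy sequences through t+1.
enum_expected_flip <- function(obs, t, psi, th0, th, thp, gamma, eps,
                               p1, p2, pi_mix) {
  S <- ncol(obs)
  num <- 0
  den <- 0
  det_t <- any(obs[t, ] == 1L, na.rm = TRUE)
  for (cls in 1:2) {
    w <- if (cls == 1L) pi_mix else 1 - pi_mix
    p <- if (cls == 1L) p1 else p2
    pd <- function(tt) 1 - enum_stop_forward(rep(0L, S), th0, th, thp, p[tt, ])
    for (mask in 0:(2^(t + 1L) - 1L)) {
      z <- as.integer(intToBits(mask))[seq_len(t + 1L)]
      pr <- if (z[1L] == 1L) psi else 1 - psi
      for (k in seq_len(t + 1L)[-1L]) {
        pr <- pr * if (z[k - 1L] == 0L) {
          if (z[k] == 1L) gamma[k - 1L] else 1 - gamma[k - 1L]
        } else {
          if (z[k] == 0L) eps[k - 1L] else 1 - eps[k - 1L]
        }
      }
      em <- 1
      for (k in seq_len(t)) {
        em <- em * if (z[k] == 1L) {
          enum_stop_forward(obs[k, ], th0, th, thp, p[k, ])
        } else {
          if (any(obs[k, ] == 1L, na.rm = TRUE)) 0 else 1
        }
      }
      joint <- w * pr * em
      den <- den + joint
      p_det_next <- if (z[t + 1L] == 1L) pd(t + 1L) else 0
      num <- num + joint * if (det_t) 1 - p_det_next else p_det_next
    }
  }
  num / den
}
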