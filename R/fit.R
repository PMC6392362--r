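#' Maximum-likelihood fit of a dynamic occupancy model structure
#'
#' Minimizes the dataset -2 log-likelihood over coefficients on the
#' log-odds scale by quasi-Newton iteration with finite-difference
#' gradients, optionally from several jittered starting points (mixture
#' likelihoods are multimodal).  Standard errors come from the inverse of a
#' numerically differentiated Hessian at the optimum; mixture classes are
#' relabeled post hoc so class 1 has the smaller detection intercept;
#' coefficients with `|logit| > 15` are flagged as boundary estimates and
#' reported as-is.
#'
#' @param data an [occu_data()] dataset.
#' @param spec a [model_spec()].
#' @param covariates prepared covariate table ([prepare_covariates()]).
#' @param n_starts number of optimizer starts (first start is unjittered).
#' @param seed seed for start jitter.
#' @param start optional named starting vector (overrides defaults).
#' @param compute_se compute the Hessian-based standard errors.
#' @param theta0_mode,dev_year conventions; see [neg2_loglik()].
#' @param control passed to [stats::nlminb()] (`rel.tol` governs the
#'   -2LL convergence tolerance; default `1e-10`).
#' @return An object of class `occu_fit` with elements `estimates`,
#'   `std_errors`, `neg2ll`, `aic`, `n_params`, `converged`, `relabeled`,
#'   `boundary`, `spec`, and optimizer metadata.
#' @export
fit_occu <- function(data, spec, covariates, n_starts = 5L, seed = 1L,
                     start = NULL, compute_se = TRUE,
                     theta0_mode = "theta", dev_year = "origin",
                     control = list()) {
  d <- build_designs(spec, data, covariates, dev_year)
  obs <- obs_array(data)
  k <- sum(d$npar)
  objective <- function(beta) {
    v <- neg2_from_designs(data, d, beta, theta0_mode, obs = obs)
    if (!is.finite(v)) 1e10 else v
  }
  base_start <- start %||% default_start(data, d)
  if (length(base_start) != k) stop("start vector has wrong length")
  ctrl <- utils::modifyList(list(rel.tol = 1e-10, iter.max = 1000L,
                                 eval.max = 2000L), control)
  # box the search on the logit scale: beyond |25| the link saturates and
  # the profile is flat, so unbounded runs can wander to +/-10^4 and rack
  # up spurious deviance; genuine boundary fits are still flagged (>15)
  box <- 25
  set.seed(seed)
  best <- NULL
  traces <- numeric(n_starts)
  for (i in seq_len(n_starts)) {
    st <- if (i == 1L) base_start else base_start + rnorm(k, 0, 0.5)
    opt <- nlminb(pmin(pmax(st, -box), box), objective, control = ctrl,
                  lower = -box, upper = box)
    traces[i] <- opt$objective
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  est <- best$par
  names(est) <- d$coef_names
  grad <- num_gradient(objective, est)
  # nlminb code 1 with message "singular convergence" marks flat directions
  # (e.g. near-collinear covariates) at an otherwise genuine optimum; accept
  # it when the gradient criterion holds, and record the message.
  opt_ok <- best$convergence == 0 ||
    grepl("singular convergence|X-convergence", best$message %||% "")
  converged <- opt_ok && is.finite(best$objective) &&
    sqrt(sum(grad^2)) < 1e-2 * max(1, abs(best$objective))
  se <- rep(NA_real_, k)
  if (compute_se) {
    H <- tryCatch(optimHess(est, objective), error = function(e) NULL)
    if (!is.null(H)) {
      # objective is -2 logL, so the information matrix is H / 2
      V <- tryCatch(solve(H / 2), error = function(e) NULL)
      if (!is.null(V)) {
        dg <- diag(V)
        se[dg > 0] <- sqrt(dg[dg > 0])
      }
    }
  }
  names(se) <- d$coef_names
  out <- structure(list(
    spec = spec, estimates = est, std_errors = se,
    neg2ll = best$objective, aic = best$objective + 2 * k, n_params = k,
    converged = converged, optimizer_message = best$message,
    relabeled = FALSE,
    boundary = abs(est) > 15,
    theta0_mode = theta0_mode, dev_year = dev_year,
    seed = seed, n_starts = n_starts, start_objectives = traces,
    years = data$years, n_routes = length(data$histories),
    n_stops = data$n_stops), class = "occu_fit")
  relabel_mixture(out)
}

# Central-difference gradient (used only for the convergence check).
num_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

# Moment-flavored starting values: intercepts from naive frequencies,
# everything else 0.
default_start <- function(data, d) {
  obs <- obs_array(data)
  det_rate <- mean(obs == 1L, na.rm = TRUE)
  yr_det <- apply(obs, c(3, 2), function(v) any(v == 1L, na.rm = TRUE))
  naive_occ <- mean(yr_det)
  clamp <- function(x) pmin(pmax(x, 0.02), 0.98)
  start <- numeric(sum(d$npar))
  names(start) <- d$coef_names
  start["psi:intercept"] <- qlogis(clamp(naive_occ + 0.1))
  start["theta:intercept"] <- qlogis(0.3)
  start["theta_prime:intercept"] <- qlogis(0.6)
  start["gamma:intercept"] <- qlogis(0.15)
  start["epsilon:intercept"] <- qlogis(0.1)
  start["p1:intercept"] <- qlogis(clamp(det_rate * 0.7))
  start["p2:intercept"] <- qlogis(clamp(det_rate * 2))
  start["pi_mix:intercept"] <- 0
  start
}

# Relabel mixture classes so class 1 has the smaller detection intercept
# (the "low-detection" class), flipping the sign of the pi_mix logit.
relabel_mixture <- function(fit) {
  nm <- names(fit$estimates)
  i1 <- match("p1:intercept", nm)
  i2 <- match("p2:intercept", nm)
  if (is.na(i1) || is.na(i2) || fit$estimates[i1] <= fit$estimates[i2]) {
    return(fit)
  }
  b1 <- grep("^p1:", nm)
  b2 <- grep("^p2:", nm)
  l1 <- sub("^p1:", "", nm[b1]); l2 <- sub("^p2:", "", nm[b2])
  if (!identical(l1, l2)) return(fit) # asymmetric structures: leave as-is
  swap <- function(v) { tmp <- v[b1]; v[b1] <- v[b2]; v[b2] <- tmp; v }
  fit$estimates <- swap(fit$estimates)
  fit$std_errors <- swap(fit$std_errors)
  fit$boundary <- swap(fit$boundary)
  ipi <- match("pi_mix:intercept", nm)
  fit$estimates[ipi] <- -fit$estimates[ipi]
  fit$relabeled <- TRUE
  fit
}

#' @export
print.occu_fit <- function(x, ...) {
  cat(sprintf("<occu_fit> %d parameters, -2LL = %.3f, AIC = %.3f, %s%s\n",
              x$n_params, x$neg2ll, x$aic,
              if (x$converged) "converged" else "NOT CONVERGED",
              if (x$relabeled) " (mixture relabeled)" else ""))
  df <- as.data.frame(x)
  print(df, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.occu_fit <- function(object, ...) object$estimates

#' @export
as.data.frame.occu_fit <- function(x, ...) {
  nm <- names(x$estimates)
  data.frame(family = sub(":.*$", "", nm),
             term = sub("^[^:]*:", "", nm),
             estimate = unname(x$estimates),
             se = unname(x$std_errors),
             boundary = unname(x$boundary))
}

#' Write fitted coefficients to CSV
#'
#' One row per term (`family`, `term`, `estimate`, `se`, `boundary`), plus
#' a JSON sidecar with fit metadata (`-2LL`, AIC, parameter count,
#' convergence, seed).
#'
#' @param fit an `occu_fit`.
#' @param path output CSV path; the sidecar is `<path>.json`.
#' @export
write_fit <- function(fit, path) {
  write.csv(as.data.frame(fit), path, row.names = FALSE)
  meta <- list(neg2ll = fit$neg2ll, aic = fit$aic,
               n_params = fit$n_params, converged = fit$converged,
               relabeled = fit$relabeled, seed = fit$seed,
               n_starts = fit$n_starts,
               theta0_mode = fit$theta0_mode, dev_year = fit$dev_year)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Sequential covariate reduction on the nuisance structure
#'
#' Starting from a fitted global structure and holding the colonization and
#' extinction blocks fixed, repeatedly removes -- within each family group
#' in `families` order -- the non-intercept term with the smallest
#' |estimate| / SE ratio, refits, and stops when AIC rises, keeping the
#' minimum-AIC structure before moving to the next group.  Terms with
#' unavailable standard errors are treated as ratio 0 (removed first).
#' Ties break lexicographically by family order then term order.
#'
#' @param data,covariates as in [fit_occu()].
#' @param global_spec the starting [model_spec()].
#' @param families list of family-name groups reduced in order; detection
#'   classes are pooled by default, as a single detection structure.
#' @param ... passed to [fit_occu()].
#' @return list with the final `spec`, the final `fit`, and a data frame
#'   `path` recording each removal.
#' @export
reduce_structure <- function(data, global_spec, covariates,
                             families = list("psi", "theta", "theta_prime",
                                             c("p1", "p2")),
                             ...) {
  spec <- global_spec
  fit <- fit_occu(data, spec, covariates, ...)
  if (!fit$converged) {
    stop("global model did not converge; cannot start reduction")
  }
  path <- data.frame(family = character(), term = character(),
                     aic_before = numeric(), aic_after = numeric())
  for (group in families) {
    repeat {
      nm <- names(fit$estimates)
      fams <- sub(":.*$", "", nm)
      terms <- sub("^[^:]*:", "", nm)
      cand <- which(fams %in% group & terms != "intercept")
      if (!length(cand)) break
      ratio <- abs(fit$estimates[cand]) / fit$std_errors[cand]
      ratio[is.na(ratio)] <- 0
      drop_i <- cand[which.min(ratio)]
      new_spec <- drop_term(spec, fams[drop_i], terms[drop_i])
      new_fit <- fit_occu(data, new_spec, covariates, ...)
      if (!new_fit$converged) {
        stop(sprintf("reduction failed: model without %s did not converge (path so far: %s)",
                     nm[drop_i],
                     paste(paste0(path$family, ":", path$term),
                           collapse = ", ")))
      }
      if (new_fit$aic > fit$aic) break
      path <- rbind(path, data.frame(family = fams[drop_i],
                                     term = terms[drop_i],
                                     aic_before = fit$aic,
                                     aic_after = new_fit$aic))
      spec <- new_spec
      fit <- new_fit
    }
  }
  list(spec = spec, fit = fit, path = path)
}

#' Starting vector for a larger spec from a smaller fit
#'
#' Carries the shared coefficients of a fitted nested model into the
#' coefficient layout of `spec`, zero-filling new terms; a cheap warm start
#' when fitting a model set.
#'
#' @param fit an `occu_fit`.
#' @param spec the target [model_spec()].
#' @export
expand_start <- function(fit, spec) {
  nm <- coef_names(spec)
  st <- stats::setNames(numeric(length(nm)), nm)
  common <- intersect(nm, names(fit$estimates))
  st[common] <- fit$estimates[common]
  st
}

drop_term <- function(spec, family, label) {
  s <- unclass(spec)
  keep <- vapply(s[[family]], function(tm) term_label(tm) != label, TRUE)
  if (all(keep)) stop(sprintf("term '%s' not found in family '%s'", label,
                              family))
  s[[family]] <- s[[family]][keep]
  do.call(model_spec, s)
}
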