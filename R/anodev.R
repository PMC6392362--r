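#' Relative deviance explained (analysis of deviance)
#'
#' `rdev2 = (Dev(M_null) - Dev(M_cov)) / (Dev(M_null) - Dev(M_full))`,
#' the fraction of the deviance improvement of the fully time-varying model
#' (relative to the spatial-only null) captured by a covariate model of
#' temporal variation.  Deviance here is -2 log-likelihood; any additive
#' constant cancels, so -2LL offsets can be supplied directly.  Values may
#' exceed 1 because the covariate models are not strictly nested within the
#' full model.
#'
#' @param dev_null deviance of the null (spatial-only) model.
#' @param dev_cov deviance of the covariate model.
#' @param dev_full deviance of the full (year-effect) model.
#' @return a fraction (not percent).
#' @examples
#' rdev2(-26.79, -21.54, 0) # 0.196
#' @export
rdev2 <- function(dev_null, dev_cov, dev_full) {
  if (dev_null == dev_full) {
    stop("rdev2 undefined: null and full model deviances are equal")
  }
  if (dev_null < dev_full) {
    warning("dev_null < dev_full: the analysis-of-deviance premise fails")
  }
  (dev_null - dev_cov) / (dev_null - dev_full)
}

#' Likelihood-ratio test between nested fits
#'
#' `chi2` is the difference in -2 log-likelihood, `df` the difference in
#' parameter counts, and `p` the upper chi-square tail.
#'
#' @param fit_reduced,fit_general `occu_fit` objects, or bare lists with
#'   `neg2ll` and `n_params` elements.
#' @param tol tolerance for a slightly negative chi-square from numerical
#'   noise (clipped to 0); a more negative value is a nesting violation.
#' @return list with `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(fit_reduced, fit_general, tol = 1e-6) {
  chi2 <- fit_reduced$neg2ll - fit_general$neg2ll
  df <- fit_general$n_params - fit_reduced$n_params
  if (chi2 < -tol) {
    stop(sprintf("nesting violation: reduced model fits better by %.3g",
                 -chi2))
  }
  chi2 <- max(chi2, 0)
  p <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else
    as.numeric(chi2 <= tol)
  list(chi2 = chi2, df = df, p = p)
}

MODEL_FLAGS <- data.frame(
  model = 1:6,
  intercept = TRUE,
  average_habitat = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
  average_climate = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
  habitat_deviation = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
  climate_deviation = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
  year_effect = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))

#' Analysis-of-deviance table from -2LL offsets
#'
#' Builds the deviance-partition table from the six models' -2LL offsets
#' relative to the full model (Model 2).  `RDev2` uses Model 3 as null and
#' Model 2 as full; it is not applicable for Model 1, 1 (100%) for Model 2,
#' and exactly 0 for Model 3.
#'
#' @param offsets named numeric (`model1 ... model6`) or plain length-6
#'   vector in model order: -2LL of each model minus -2LL of Model 2
#'   (so `model2 = 0`, others >= 0... note offsets are conventionally
#'   reported as negative Delta(-2LL) improvements *of Model 2 over each
#'   model*, i.e. `-2LL(model) - (-2LL(model2))` times -1; both sign
#'   conventions are accepted, see Details).
#' @details Internally only differences enter the ratio, so offsets may be
#'   given either as `-2LL(m) - (-2LL(m2))` (nonnegative) or with the
#'   opposite sign (nonpositive, as conventionally tabulated); the table
#'   reproduces the same `RDev2` either way.
#' @return data frame with the covariate flags, `delta_neg2ll` (as given)
#'   and `rdev2_pct`.
#' @examples
#' anodev_from_offsets(c(model1 = -70.98, model2 = 0, model3 = -26.79,
#'                       model4 = -21.54, model5 = -26.67, model6 = -21.38))
#' @export
anodev_from_offsets <- function(offsets) {
  if (!is.null(names(offsets))) {
    offsets <- offsets[paste0("model", 1:6)]
  }
  if (length(offsets) != 6L || anyNA(offsets)) {
    stop("need six finite offsets, model1 ... model6")
  }
  dev <- -offsets # deviance up to a constant; sign-symmetric in the ratio
  denom_zero <- dev[3L] == dev[2L]
  r <- vapply(1:6, function(m) {
    if (m == 1L) return(NA_real_)
    if (denom_zero) return(NA_real_)
    rdev2(dev[3L], dev[m], dev[2L])
  }, 0)
  if (denom_zero) {
    warning("Model 2 and Model 3 deviances are equal: RDev2 degenerate")
  }
  out <- MODEL_FLAGS
  out$delta_neg2ll <- unname(offsets)
  out$rdev2_pct <- 100 * r
  class(out) <- c("anodev_table", "data.frame")
  out
}

#' Analysis-of-deviance table from six fitted models
#'
#' @param fits named list `model1 ... model6` of converged [fit_occu()]
#'   results sharing dataset and nuisance structure.
#' @return data frame as in [anodev_from_offsets()], with the offsets
#'   computed as `-(neg2ll(model) - neg2ll(model2))` (so better-fitting
#'   Model 2 gives the other models negative offsets), plus `n_params` and
#'   `aic` columns.
#' @export
anodev_table <- function(fits) {
  if (!all(paste0("model", 1:6) %in% names(fits))) {
    stop("'fits' must be a named list model1 ... model6")
  }
  fits <- fits[paste0("model", 1:6)]
  if (!all(vapply(fits, function(f) isTRUE(f$converged), TRUE))) {
    warning("not all of the six models converged")
  }
  n2 <- vapply(fits, `[[`, 0, "neg2ll")
  sizes <- vapply(fits, function(f) f$n_routes %||% NA_integer_, 0)
  if (length(unique(sizes[!is.na(sizes)])) > 1L) {
    stop("the six fits are not on the same dataset")
  }
  offsets <- -(n2 - n2[["model2"]])
  out <- anodev_from_offsets(offsets)
  out$neg2ll <- unname(n2)
  out$n_params <- vapply(fits, `[[`, 0L, "n_params")
  out$aic <- vapply(fits, `[[`, 0, "aic")
  out
}

#' @export
print.anodev_table <- function(x, ...) {
  cat("Analysis of deviance for colonization/extinction models\n")
  df <- as.data.frame(x)
  flags <- c("intercept", "average_habitat", "average_climate",
             "habitat_deviation", "climate_deviation", "year_effect")
  for (f in flags) df[[f]] <- ifelse(df[[f]], "X", "")
  ord <- order(-df$delta_neg2ll)
  print(df[ord, ], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Corrected AIC
#'
#' @param fit an `occu_fit`.
#' @param n effective sample size (default: number of routes).
#' @export
aicc <- function(fit, n = fit$n_routes) {
  k <- fit$n_params
  fit$neg2ll + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}
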