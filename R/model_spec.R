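#' Model-structure terms
#'
#' A `model_spec` assigns each parameter family an ordered list of terms.
#' Available term constructors:
#' * `t_intercept()` — the family intercept (mandatory, always first);
#' * `t_cov(name, component)` — a standardized covariate, entering as its
#'   per-route temporal mean (`"mean"`), its annual deviation from that mean
#'   (`"deviation"`), or its first-study-year value (`"first_year"`);
#' * `t_year(year)` — a dummy for one calendar year (for colonization and
#'   extinction the dummy is indexed by the destination year of the
#'   transition);
#' * `t_stop(power)` — the z-scaled stop index raised to `power`, a proxy
#'   for time of day in the detection model.
#' @param name covariate base name (must match the covariate table).
#' @param component one of `"mean"`, `"deviation"`, `"first_year"`.
#' @param year calendar year.
#' @param power polynomial power of the scaled stop index.
#' @name spec-terms
NULL

#' @rdname spec-terms
#' @export
t_intercept <- function() structure(list(type = "intercept"), class = "occu_term")

#' @rdname spec-terms
#' @export
t_cov <- function(name, component = c("mean", "deviation", "first_year")) {
  component <- match.arg(component)
  structure(list(type = "covariate", name = name, component = component),
            class = "occu_term")
}

#' @rdname spec-terms
#' @export
t_year <- function(year) {
  structure(list(type = "year_dummy", year = as.integer(year)),
            class = "occu_term")
}

#' @rdname spec-terms
#' @export
t_stop <- function(power = 1L) {
  structure(list(type = "stop_poly", power = as.integer(power)),
            class = "occu_term")
}

term_label <- function(term) {
  switch(term$type,
         intercept = "intercept",
         covariate = paste0(term$name, "_", term$component),
         year_dummy = paste0("year", term$year),
         stop_poly = if (term$power == 1L) "stop" else
           paste0("stop^", term$power))
}

FAMILIES <- c("psi", "theta", "theta_prime", "gamma", "epsilon",
              "p1", "p2", "pi_mix")

#' Symbolic model structure for the dynamic occupancy model
#'
#' @param psi,theta,theta_prime,gamma,epsilon,p1,p2,pi_mix lists of terms
#'   built with the [spec-terms] constructors.  Every family must start
#'   with an intercept; `pi_mix` (the mixture weight, a scalar on the
#'   log-odds scale) admits only an intercept.  Covariate terms are not
#'   supported in the detection families `p1`/`p2` (year dummies and stop
#'   polynomial only), mirroring the default detection structure.
#' @return An object of class `model_spec`.
#' @seealso [global_model_spec()], [build_model_set()], [count_parameters()]
#' @export
model_spec <- function(psi = list(t_intercept()),
                       theta = list(t_intercept()),
                       theta_prime = list(t_intercept()),
                       gamma = list(t_intercept()),
                       epsilon = list(t_intercept()),
                       p1 = list(t_intercept()),
                       p2 = list(t_intercept()),
                       pi_mix = list(t_intercept())) {
  fams <- list(psi = psi, theta = theta, theta_prime = theta_prime,
               gamma = gamma, epsilon = epsilon, p1 = p1, p2 = p2,
               pi_mix = pi_mix)
  for (fam in names(fams)) {
    terms <- fams[[fam]]
    if (!length(terms) || terms[[1L]]$type != "intercept") {
      stop(sprintf("family '%s' must start with an intercept term", fam))
    }
    labs <- vapply(terms, term_label, "")
    if (anyDuplicated(labs)) {
      stop(sprintf("duplicate term '%s' in family '%s'",
                   labs[anyDuplicated(labs)], fam))
    }
    if (fam == "pi_mix" && length(terms) > 1L) {
      stop("pi_mix admits only an intercept")
    }
    if (fam %in% c("p1", "p2") &&
        any(vapply(terms, `[[`, "", "type") == "covariate")) {
      stop("covariate terms are not supported in detection families")
    }
    if (fam %in% c("psi", "theta", "theta_prime") &&
        any(vapply(terms, `[[`, "", "type") %in%
            c("year_dummy", "stop_poly"))) {
      stop(sprintf("family '%s' admits intercept and covariate terms only", fam))
    }
    if (fam %in% c("gamma", "epsilon") &&
        any(vapply(terms, `[[`, "", "type") == "stop_poly")) {
      stop("stop terms are not meaningful for gamma/epsilon")
    }
  }
  structure(fams, class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", count_parameters(x), "parameters\n")
  for (fam in FAMILIES) {
    cat(sprintf("  %-12s %s\n", fam,
                paste(vapply(x[[fam]], term_label, ""), collapse = " + ")))
  }
  invisible(x)
}

#' Total number of free parameters in a model structure
#'
#' @param spec a [model_spec()].
#' @return integer count (one per term).
#' @export
count_parameters <- function(spec) {
  sum(vapply(unclass(spec), length, 0L))
}

coef_names <- function(spec) {
  unlist(lapply(FAMILIES, function(fam) {
    paste0(fam, ":", vapply(spec[[fam]], term_label, ""))
  }))
}

#' The fully parameterized (global) model structure
#'
#' Builds the conventional global structure: initial occupancy and the two
#' availability parameters are modeled on habitat and climate covariates,
#' colonization/extinction get an intercept, year dummies (all transition
#' destination years after the first) and spatial covariate means, and both
#' detection classes get year dummies plus a quadratic stop polynomial.
#' With 16 study years and the default one habitat + two climate covariates
#' this yields 85 parameters.
#'
#' @param years the study years (calendar years of the dataset).
#' @param habitat,climate covariate base names.
#' @param psi_component covariate component for initial occupancy
#'   (default the first-study-year value).
#' @param availability_component covariate component for `theta`,
#'   `theta_prime` (default the route mean).
#' @param stop_degree degree of the stop polynomial in the detection model.
#' @export
global_model_spec <- function(years, habitat = "habitat",
                              climate = c("heat", "cold"),
                              psi_component = "first_year",
                              availability_component = "mean",
                              stop_degree = 2L) {
  years <- as.integer(years)
  covs <- c(habitat, climate)
  cov_terms <- function(component) lapply(covs, t_cov, component = component)
  ge_terms <- c(list(t_intercept()),
                lapply(years[-(1:2)], t_year),
                cov_terms("mean"))
  p_terms <- c(list(t_intercept()),
               lapply(years[-1L], t_year),
               lapply(seq_len(stop_degree), t_stop))
  model_spec(
    psi = c(list(t_intercept()), cov_terms(psi_component)),
    theta = c(list(t_intercept()), cov_terms(availability_component)),
    theta_prime = c(list(t_intercept()), cov_terms(availability_component)),
    gamma = ge_terms, epsilon = ge_terms,
    p1 = p_terms, p2 = p_terms)
}

#' The six-model set on colonization and extinction
#'
#' Given a base structure (typically the output of [reduce_structure()] or
#' [global_model_spec()]), returns the six nested-to-quasi-nested structures
#' whose deviances drive the analysis-of-deviance partition:
#' 1. null — intercept only;
#' 2. global — intercept + year dummies + spatial covariate means;
#' 3. spatial — intercept + covariate means;
#' 4. spatial + climate deviations;
#' 5. spatial + habitat deviation;
#' 6. spatial + climate and habitat deviations.
#' All other families are carried over unchanged from `base_spec`.
#'
#' @param base_spec a [model_spec()] providing the shared nuisance
#'   structure.
#' @param years study years (for the year dummies of Model 2).
#' @param habitat,climate covariate base names (may be empty).
#' @return named list `model1 ... model6` of [model_spec()] objects.
#' @export
build_model_set <- function(base_spec, years, habitat = "habitat",
                            climate = c("heat", "cold")) {
  years <- as.integer(years)
  covs <- c(habitat, climate)
  means <- lapply(covs, t_cov, component = "mean")
  devs <- function(nms) lapply(nms, t_cov, component = "deviation")
  blocks <- list(
    model1 = list(t_intercept()),
    model2 = c(list(t_intercept()), lapply(years[-(1:2)], t_year), means),
    model3 = c(list(t_intercept()), means),
    model4 = c(list(t_intercept()), means, devs(climate)),
    model5 = c(list(t_intercept()), means, devs(habitat)),
    model6 = c(list(t_intercept()), means, devs(c(habitat, climate))))
  lapply(blocks, function(b) {
    s <- unclass(base_spec)
    s$gamma <- b
    s$epsilon <- b
    do.call(model_spec, s)
  })
}

# ---- design matrices -------------------------------------------------------

# Lookup of covariate columns as route x year matrices aligned to the data.
cov_matrix <- function(covariates, column, route_ids, years) {
  if (!column %in% names(covariates)) {
    stop(sprintf("covariate column '%s' not found (run prepare_covariates())",
                 column))
  }
  key <- paste(covariates$route_id, covariates$year)
  idx <- match(paste(rep(route_ids, times = length(years)),
                     rep(years, each = length(route_ids))), key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1L]
    stop(sprintf("covariate '%s' missing for route %s, year %d", column,
                 rep(route_ids, times = length(years))[miss],
                 rep(years, each = length(route_ids))[miss]))
  }
  matrix(covariates[[column]][idx], nrow = length(route_ids))
}

# Build the design matrix for one family.  Row ordering conventions match
# the reshapes in params_from_beta():
#   route-level families: one row per route;
#   gamma/epsilon: route fastest within transition (R x (T-1) column-major);
#   p1/p2: stop fastest within year (S x T column-major).
family_design <- function(fam, terms, data, covariates, dev_year) {
  R <- length(data$histories); T <- length(data$years); S <- data$n_stops
  years <- data$years
  ids <- data$route_ids
  col_for <- function(term, at_rows) {
    if (term$type == "intercept") return(rep(1, at_rows))
    stop("unreachable")
  }
  if (fam %in% c("psi", "theta", "theta_prime")) {
    cols <- lapply(terms, function(tm) {
      switch(tm$type,
             intercept = rep(1, R),
             covariate = {
               if (tm$component == "deviation") {
                 stop(sprintf("deviation components are not defined for route-level family '%s'", fam))
               }
               column <- if (tm$component == "mean")
                 paste0(tm$name, "_mean") else paste0(tm$name, "_z")
               m <- cov_matrix(covariates, column, ids, years)
               if (tm$component == "mean") m[, 1L] else m[, 1L]
             })
    })
  } else if (fam %in% c("gamma", "epsilon")) {
    nT <- max(T - 1L, 0L)
    dest <- years[-1L]
    orig <- years[-T]
    cov_year <- if (dev_year == "origin") orig else dest
    cols <- lapply(terms, function(tm) {
      switch(tm$type,
             intercept = rep(1, R * nT),
             year_dummy = as.numeric(rep(dest == tm$year, each = R)),
             covariate = {
               if (tm$component == "mean") {
                 m <- cov_matrix(covariates, paste0(tm$name, "_mean"), ids, years)
                 rep(m[, 1L], times = nT)
               } else if (tm$component == "deviation") {
                 m <- cov_matrix(covariates, paste0(tm$name, "_dev"), ids, years)
                 as.vector(m[, match(cov_year, years), drop = FALSE])
               } else {
                 m <- cov_matrix(covariates, paste0(tm$name, "_z"), ids, years)
                 rep(m[, 1L], times = nT)
               }
             })
    })
  } else if (fam %in% c("p1", "p2")) {
    sstd <- as.vector(scale(seq_len(S)))
    if (S == 1L) sstd <- 0
    cols <- lapply(terms, function(tm) {
      switch(tm$type,
             intercept = rep(1, S * T),
             year_dummy = as.numeric(rep(years == tm$year, each = S)),
             stop_poly = rep(sstd^tm$power, times = T))
    })
  } else { # pi_mix
    cols <- list(1)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- vapply(terms, term_label, "")
  X
}

# Precompute all design matrices for a spec on a dataset.
build_designs <- function(spec, data, covariates,
                          dev_year = c("origin", "destination")) {
  dev_year <- match.arg(dev_year)
  designs <- lapply(FAMILIES, function(fam) {
    family_design(fam, spec[[fam]], data, covariates, dev_year)
  })
  names(designs) <- FAMILIES
  structure(list(designs = designs,
                 npar = vapply(designs, ncol, 0L),
                 coef_names = coef_names(spec),
                 R = length(data$histories), T = length(data$years),
                 S = data$n_stops),
            class = "occu_designs")
}

# Map a coefficient vector (log-odds scale, canonical family order) to the
# natural-scale parameter arrays consumed by the compiled likelihood.
params_from_beta <- function(d, beta, theta0_mode = "theta") {
  split_at <- cumsum(d$npar)
  idx <- function(fam) {
    i <- match(fam, FAMILIES)
    seq.int(if (i == 1L) 1L else split_at[i - 1L] + 1L, split_at[i])
  }
  lin <- function(fam) as.vector(d$designs[[fam]] %*% beta[idx(fam)])
  R <- d$R; T <- d$T; S <- d$S
  theta <- plogis(lin("theta"))
  theta_prime <- plogis(lin("theta_prime"))
  list(psi = plogis(lin("psi")),
       theta = theta, theta_prime = theta_prime,
       theta0 = theta0_value(theta, theta_prime, theta0_mode),
       gamma = matrix(plogis(lin("gamma")), R, max(T - 1L, 0L)),
       epsilon = matrix(plogis(lin("epsilon")), R, max(T - 1L, 0L)),
       p1 = matrix(plogis(lin("p1")), S, T),
       p2 = matrix(plogis(lin("p2")), S, T),
       pi_mix = plogis(lin("pi_mix")))
}

#' Dataset -2 log-likelihood at a coefficient vector
#'
#' Evaluates minus twice the log-likelihood of a detection-history dataset
#' under a [model_spec()], with per-route parameters built from `beta` by
#' the logistic link and the spec's design rows.  Returns `+Inf` (with
#' attribute `zero_likelihood = TRUE`) if any route has likelihood zero,
#' signalling data/model incompatibility.
#'
#' @param data an [occu_data()] dataset.
#' @param beta coefficient vector on the log-odds scale, ordered psi,
#'   theta, theta_prime, gamma, epsilon, p1, p2, pi_mix.
#' @param spec a [model_spec()].
#' @param covariates a prepared covariate table ([prepare_covariates()]).
#' @param theta0_mode first-stop availability convention (see
#'   [route_likelihood()]).
#' @param dev_year whether the deviation covariate of a transition is taken
#'   at its origin or destination year.
#' @export
neg2_loglik <- function(data, beta, spec, covariates,
                        theta0_mode = "theta", dev_year = "origin") {
  d <- build_designs(spec, data, covariates, dev_year)
  if (length(beta) != sum(d$npar)) {
    stop(sprintf("beta has length %d; spec needs %d", length(beta),
                 sum(d$npar)))
  }
  neg2_from_designs(data, d, beta, theta0_mode)
}

neg2_from_designs <- function(data, d, beta, theta0_mode = "theta",
                              obs = NULL) {
  pars <- params_from_beta(d, beta, theta0_mode)
  obs <- obs %||% obs_array(data)
  val <- cpp_dataset_neg2ll(as.integer(obs), d$S, d$T, d$R,
                            pars$psi, pars$theta0, pars$theta,
                            pars$theta_prime, pars$gamma, pars$epsilon,
                            pars$p1, pars$p2, pars$pi_mix)
  if (!is.finite(val)) attr(val, "zero_likelihood") <- TRUE
  val
}
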