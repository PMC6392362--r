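#' Run configuration
#'
#' Validated bag of settings for [run_pipeline()].  Unknown keys are
#' rejected; the object round-trips losslessly through JSON (or YAML when
#' the `yaml` package is available).
#'
#' @param detections path to the detection-history CSV.
#' @param covariates path to the raw covariate CSV (`route_id`, `year`,
#'   one column per covariate).
#' @param out_dir output directory for the artifact bundle.
#' @param species free-text label carried into outputs.
#' @param habitat,climate covariate names for the model set.
#' @param reduce run the sequential covariate-reduction protocol before
#'   fitting the model set (slow; off by default).
#' @param n_starts,seed fitting options.
#' @param gof_bins,gof_min_expected,gof_conditioning goodness-of-fit
#'   options.
#' @param theta0_mode,dev_year,standardize_order exposed convention
#'   switches.
#' @export
run_config <- function(detections, covariates, out_dir,
                       species = "species",
                       habitat = "habitat", climate = c("heat", "cold"),
                       reduce = FALSE, n_starts = 1L, seed = 1L,
                       gof_bins = 10L, gof_min_expected = 4,
                       gof_conditioning = "full_history",
                       theta0_mode = "theta", dev_year = "origin",
                       standardize_order = "standardize_first") {
  cfg <- list(detections = detections, covariates = covariates,
              out_dir = out_dir, species = species, habitat = habitat,
              climate = climate, reduce = reduce,
              n_starts = as.integer(n_starts), seed = as.integer(seed),
              gof_bins = as.integer(gof_bins),
              gof_min_expected = gof_min_expected,
              gof_conditioning = gof_conditioning,
              theta0_mode = theta0_mode, dev_year = dev_year,
              standardize_order = standardize_order)
  structure(cfg, class = "run_config")
}

#' Read/write a run configuration
#'
#' Format is chosen by extension: `.json` via jsonlite, `.yaml`/`.yml` via
#' the yaml package.  Unknown keys in the file are an error.
#'
#' @param path config file path.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the 'yaml' package; use JSON instead")
    }
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Run the full inference pipeline
#'
#' Reads detections and covariates, optionally reduces the nuisance
#' structure of the global model, fits the six colonization/extinction
#' models, computes the analysis-of-deviance table and the
#' Hosmer-Lemeshow goodness-of-fit tests, and writes the artifact bundle:
#' per-model coefficient CSVs (with JSON sidecars), `anodev.csv`,
#' `gof.json`, and `provenance.json`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `fits`, `anodev`, `gof`, `spec`, and
#'   `out_dir`; on a stage failure the bundle is marked partial with the
#'   failing stage recorded in `provenance.json`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config = unclass(config), started = format(Sys.time()),
               package_version = as.character(utils::packageVersion("occpart")),
               status = "partial", failed_stage = NULL)
  result <- list(out_dir = config$out_dir)
  stage <- function(name, expr) {
    message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      prov$failed_stage <<- name
      prov$error <<- conditionMessage(e)
      jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  data <- stage("read_detections", read_detections(config$detections))
  covs <- stage("prepare_covariates", {
    raw <- read.csv(config$covariates)
    prepare_covariates(raw, names = c(config$habitat, config$climate),
                       order = config$standardize_order)
  })
  base <- stage("base_structure", {
    gspec <- global_model_spec(data$years, config$habitat, config$climate)
    if (config$reduce) {
      reduce_structure(data, gspec, covs, n_starts = config$n_starts,
                       seed = config$seed, theta0_mode = config$theta0_mode,
                       dev_year = config$dev_year)$spec
    } else gspec
  })
  fits <- stage("fit_model_set", {
    specs <- build_model_set(base, data$years, config$habitat,
                             config$climate)
    # fit the spatial-only model first; warm-start the rest from it so the
    # nesting order holds even at local optima
    f3 <- fit_occu(data, specs$model3, covs, n_starts = config$n_starts,
                   seed = config$seed, theta0_mode = config$theta0_mode,
                   dev_year = config$dev_year)
    fits <- lapply(specs[names(specs) != "model3"], function(sp) {
      fit_occu(data, sp, covs, n_starts = config$n_starts,
               seed = config$seed, start = expand_start(f3, sp),
               theta0_mode = config$theta0_mode, dev_year = config$dev_year)
    })
    fits$model3 <- f3
    fits[paste0("model", 1:6)]
  })
  for (m in names(fits)) {
    write_fit(fits[[m]], file.path(config$out_dir,
                                   sprintf("coefficients_%s.csv", m)))
  }
  anodev <- stage("anodev", anodev_table(fits))
  write.csv(as.data.frame(anodev), file.path(config$out_dir, "anodev.csv"),
            row.names = FALSE)
  gof <- stage("gof", gof_naive_rates(fits$model2, data, covs,
                                      n_bins = config$gof_bins,
                                      min_expected = config$gof_min_expected,
                                      conditioning = config$gof_conditioning))
  jsonlite::write_json(
    lapply(gof, function(g) if (is.null(g)) NULL else
      g[c("chi2", "df", "p")]),
    file.path(config$out_dir, "gof.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  for (rate in names(gof)) {
    if (!is.null(gof[[rate]])) {
      write.csv(gof[[rate]]$bins,
                file.path(config$out_dir, sprintf("gof_bins_%s.csv", rate)),
                row.names = FALSE)
    }
  }
  prov$status <- "complete"
  prov$neg2ll <- lapply(fits, `[[`, "neg2ll")
  prov$finished <- format(Sys.time())
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(fits = fits, anodev = anodev, gof = gof, spec = base,
                 out_dir = config$out_dir))
}
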