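#' Hourly temperatures from daily extremes
#'
#' Reconstructs a 24-hour temperature curve from the day's minimum and
#' maximum and the next day's minimum, using sinusoidal segments for the
#' daytime rise (minimum at sunrise, maximum at the peak hour) and fall, and
#' a square-root-of-time nocturnal decay from the sunset temperature toward
#' the next sunrise minimum.  The sunset anchor is
#' `tmax - c_decay * (tmax - tmin_tomorrow)`.  Pre-sunrise hours continue
#' the previous night's decay, ending at `tmin_today` at sunrise; when the
#' previous sunset temperature is not supplied it defaults to the
#' self-similar-day value.
#'
#' Timing constants are fixed defaults rather than station-calibrated
#' values; they are exposed as arguments.
#'
#' @param tmin_today,tmax_today,tmin_tomorrow daily temperatures, degrees C.
#' @param sunrise,peak,sunset timing in hours (must be ordered).
#' @param c_decay fraction of the max-to-next-min drop realized by sunset.
#' @param t_sunset_prev previous day's sunset temperature (optional).
#' @return numeric vector of 24 values, one per hour 0..23.
#' @examples
#' interpolate_hourly(10, 30, 12)
#' @export
interpolate_hourly <- function(tmin_today, tmax_today, tmin_tomorrow,
                               sunrise = 6, peak = 15, sunset = 20,
                               c_decay = 0.39, t_sunset_prev = NULL) {
  if (tmin_today > tmax_today) {
    stop("tmin_today must not exceed tmax_today")
  }
  if (!(sunrise < peak && peak < sunset && sunset <= 24)) {
    stop("timing must satisfy sunrise < peak < sunset <= 24")
  }
  ts_today <- tmax_today - c_decay * (tmax_today - tmin_tomorrow)
  ts_prev <- t_sunset_prev %||%
    (tmax_today - c_decay * (tmax_today - tmin_today))
  night_len <- 24 - sunset + sunrise
  h <- 0:23
  out <- numeric(24)
  pre <- h < sunrise
  out[pre] <- ts_prev + (tmin_today - ts_prev) *
    sqrt(h[pre] + 24 - sunset) / sqrt(night_len)
  rise <- h >= sunrise & h <= peak
  out[rise] <- tmin_today + (tmax_today - tmin_today) *
    sin(pi / 2 * (h[rise] - sunrise) / (peak - sunrise))
  fall <- h > peak & h <= sunset
  out[fall] <- ts_today + (tmax_today - ts_today) *
    sin(pi / 2 * (1 + (h[fall] - peak) / (sunset - peak)))
  post <- h > sunset
  out[post] <- ts_today + (tmin_tomorrow - ts_today) *
    sqrt(h[post] - sunset) / sqrt(night_len)
  out
}

#' Hourly series for a run of days
#'
#' Applies [interpolate_hourly()] day by day, chaining the nocturnal decay
#' through the actual previous sunset temperature.  The last day reuses its
#' own minimum as the next-day minimum.
#'
#' @param daily data frame with columns `date` (Date or ISO string),
#'   `tmin_c`, `tmax_c`, contiguous in time.
#' @inheritParams interpolate_hourly
#' @return data frame with columns `date`, `hour`, `temp_c`.
#' @export
interpolate_hourly_series <- function(daily, sunrise = 6, peak = 15,
                                      sunset = 20, c_decay = 0.39) {
  daily$date <- as.Date(daily$date)
  daily <- daily[order(daily$date), ]
  if (nrow(daily) > 1L && any(diff(daily$date) != 1)) {
    gap <- daily$date[which(diff(daily$date) != 1)[1L]]
    stop(sprintf("daily series has a gap after %s", format(gap)))
  }
  n <- nrow(daily)
  tmin_next <- c(daily$tmin_c[-1L], daily$tmin_c[n])
  temps <- matrix(NA_real_, 24, n)
  ts_prev <- NULL
  for (i in seq_len(n)) {
    temps[, i] <- interpolate_hourly(daily$tmin_c[i], daily$tmax_c[i],
                                     tmin_next[i], sunrise, peak, sunset,
                                     c_decay, t_sunset_prev = ts_prev)
    ts_prev <- daily$tmax_c[i] - c_decay * (daily$tmax_c[i] - tmin_next[i])
  }
  data.frame(date = rep(daily$date, each = 24L),
             hour = rep(0:23, times = n),
             temp_c = as.vector(temps))
}

# Breeding-cycle year (June 1 - May 31, labeled by the ending calendar year)
cycle_year <- function(date) {
  d <- as.POSIXlt(date)
  d$year + 1900L + as.integer(d$mon >= 5L)
}

#' Annual thermal-stress hours over breeding-cycle years
#'
#' Counts hours strictly above the heat threshold and strictly below the
#' cold threshold within each June 1 - May 31 cycle, labeled by the calendar
#' year in which the cycle ends.  Incomplete cycles are an error.
#'
#' @param hourly data frame with columns `date`, `hour`, `temp_c`
#'   (as from [interpolate_hourly_series()]).
#' @param hot_threshold,cold_threshold degrees C.
#' @return data frame with columns `year`, `heat_hours`, `cold_hours`.
#' @export
stress_hours <- function(hourly, hot_threshold = 38, cold_threshold = 18) {
  cy <- cycle_year(as.Date(hourly$date))
  out <- data.frame(
    year = sort(unique(cy)),
    heat_hours = as.vector(tapply(hourly$temp_c > hot_threshold, cy, sum)),
    cold_hours = as.vector(tapply(hourly$temp_c < cold_threshold, cy, sum)))
  expected <- vapply(out$year, function(y) {
    24L * as.integer(as.Date(sprintf("%d-06-01", y)) -
                       as.Date(sprintf("%d-06-01", y - 1L)))
  }, 0L)
  got <- as.vector(table(cy))
  if (any(got != expected)) {
    i <- which(got != expected)[1L]
    stop(sprintf("incomplete breeding-cycle year %d: %d of %d hours present",
                 out$year[i], got[i], expected[i]))
  }
  rownames(out) <- NULL
  out
}

#' Trailing moving average
#'
#' Mean over the `window` values ending at each position; the result is
#' labeled by the ending position (names are carried over when `x` is
#' named).
#'
#' @param x numeric series, oldest first.
#' @param window window length in entries (years).
#' @export
moving_average <- function(x, window = 15L) {
  n <- length(x)
  if (n < window) {
    stop(sprintf("series of length %d is shorter than window %d", n, window))
  }
  cs <- cumsum(c(0, x))
  out <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  if (!is.null(names(x))) names(out) <- names(x)[window:n]
  out
}

#' Map land-cover snapshot fractions onto study years
#'
#' Snapshot habitat fractions are stepped onto the full study span: the 2001
#' value covers years through 2001, the 2006 value covers 2002-2006, and the
#' 2011 value covers 2007 onward.
#'
#' @param frac_2001,frac_2006,frac_2011 habitat fractions in `[0, 1]`.
#' @param years years to cover (default 1997-2012).
#' @return named numeric vector over `years`.
#' @export
assign_landcover_years <- function(frac_2001, frac_2006, frac_2011,
                                   years = 1997:2012) {
  .assert_prob(c(frac_2001, frac_2006, frac_2011), "habitat fraction")
  out <- ifelse(years <= 2001, frac_2001,
                ifelse(years <= 2006, frac_2006, frac_2011))
  names(out) <- years
  out
}

#' z-transformation with reusable parameters
#'
#' Centers and scales by the population (divide-by-n) standard deviation.
#' The center/scale used are stored as attributes so the same transform can
#' be replayed on new data via `center`/`scale`.
#'
#' @param x numeric vector.
#' @param center,scale optional pre-computed transform parameters.
#' @export
standardize <- function(x, center = NULL, scale = NULL) {
  center <- center %||% mean(x)
  scale <- scale %||% sqrt(mean((x - mean(x))^2))
  if (scale == 0) stop("cannot standardize a zero-variance covariate")
  structure((x - center) / scale, center = center, scale = scale)
}

#' Split route-year series into spatial means and temporal deviations
#'
#' For each route, the temporal mean captures purely spatial variation and
#' the annual deviation from that mean captures purely temporal variation;
#' their sum reconstructs the input exactly.
#'
#' @param df data frame with columns `route_id`, `year`, and `value`.
#' @return `df` with added columns `mean` and `dev`.
#' @export
decompose_covariate <- function(df) {
  m <- ave(df$value, df$route_id)
  df$mean <- m
  df$dev <- df$value - m
  df
}

#' Prepare a raw covariate table for modeling
#'
#' Adds, for each covariate, a standardized column `<name>_z` and its
#' spatial-mean / temporal-deviation split `<name>_mean`, `<name>_dev`.
#' By default each covariate is z-transformed over the full route-by-year
#' stack first and then decomposed; `order = "decompose_first"` decomposes
#' the raw values and standardizes each component separately.
#'
#' @param covariates data frame with columns `route_id`, `year`, and one
#'   column per raw covariate.
#' @param names covariate column names to prepare.
#' @param order `"standardize_first"` (default) or `"decompose_first"`.
#' @return the augmented data frame, with the transform parameters in
#'   attribute `scaling`.
#' @export
prepare_covariates <- function(covariates,
                               names = c("habitat", "heat", "cold"),
                               order = c("standardize_first",
                                         "decompose_first")) {
  order <- match.arg(order)
  scaling <- list()
  for (nm in names) {
    if (!nm %in% colnames(covariates)) {
      stop(sprintf("covariate column '%s' not found", nm))
    }
    if (order == "standardize_first") {
      z <- standardize(covariates[[nm]])
      scaling[[nm]] <- attributes(z)[c("center", "scale")]
      d <- decompose_covariate(data.frame(route_id = covariates$route_id,
                                          year = covariates$year,
                                          value = as.vector(z)))
      covariates[[paste0(nm, "_z")]] <- d$value
      covariates[[paste0(nm, "_mean")]] <- d$mean
      covariates[[paste0(nm, "_dev")]] <- d$dev
    } else {
      d <- decompose_covariate(data.frame(route_id = covariates$route_id,
                                          year = covariates$year,
                                          value = covariates[[nm]]))
      zm <- standardize(d$mean)
      zd <- standardize(d$dev)
      scaling[[nm]] <- list(mean = attributes(zm)[c("center", "scale")],
                            dev = attributes(zd)[c("center", "scale")])
      covariates[[paste0(nm, "_z")]] <- as.vector(zm) + as.vector(zd)
      covariates[[paste0(nm, "_mean")]] <- as.vector(zm)
      covariates[[paste0(nm, "_dev")]] <- as.vector(zd)
    }
  }
  attr(covariates, "scaling") <- scaling
  covariates
}

#' Build the route-by-year covariate table from raw inputs
#'
#' End-to-end covariate engineering: hourly interpolation of daily
#' temperature extremes, thermal-stress hours per breeding-cycle year, a
#' trailing moving average (year `Y` is assigned the window of cycles
#' ending with the cycle that ends May 31 of `Y`), the land-cover year
#' mapping, and the standardize/decompose stage.
#'
#' @param daily_temp data frame `route_id`, `date`, `tmin_c`, `tmax_c`.
#' @param landcover data frame `route_id`, `frac_2001`, `frac_2006`,
#'   `frac_2011`.
#' @param years modeled years.
#' @param window moving-average window in cycles.
#' @param hot_threshold,cold_threshold stress thresholds, degrees C.
#' @param prepare also run [prepare_covariates()] on the result.
#' @return covariate table with columns `route_id`, `year`,
#'   `habitat`, `heat`, `cold` (raw) and, if `prepare`, the standardized
#'   columns.
#' @export
build_route_covariates <- function(daily_temp, landcover,
                                   years = 1997:2012, window = 15L,
                                   hot_threshold = 38, cold_threshold = 18,
                                   prepare = TRUE) {
  parts <- lapply(split(daily_temp, daily_temp$route_id), function(d) {
    hourly <- interpolate_hourly_series(d[c("date", "tmin_c", "tmax_c")])
    ann <- stress_hours(hourly, hot_threshold, cold_threshold)
    heat <- moving_average(stats::setNames(ann$heat_hours, ann$year), window)
    cold <- moving_average(stats::setNames(ann$cold_hours, ann$year), window)
    if (!all(as.character(years) %in% names(heat))) {
      stop(sprintf("route %s: smoothed climate series does not cover %d-%d",
                   d$route_id[1L], min(years), max(years)))
    }
    data.frame(route_id = d$route_id[1L], year = years,
               heat = unname(heat[as.character(years)]),
               cold = unname(cold[as.character(years)]))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  hab <- do.call(rbind, lapply(seq_len(nrow(landcover)), function(i) {
    data.frame(route_id = landcover$route_id[i], year = years,
               habitat = unname(assign_landcover_years(
                 landcover$frac_2001[i], landcover$frac_2006[i],
                 landcover$frac_2011[i], years)))
  }))
  out <- merge(out, hab, by = c("route_id", "year"), sort = FALSE)
  out <- out[order(out$route_id, out$year), c("route_id", "year", "habitat",
                                              "heat", "cold")]
  rownames(out) <- NULL
  if (prepare) prepare_covariates(out) else out
}
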