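#' Stop-level detection history for one survey route
#'
#' Container for the binary stop-level observations of a single route across
#' consecutive breeding seasons.  `obs` is a year-by-stop matrix with entries
#' 0 (no detection), 1 (detection) or `NA` (stop not surveyed).  Seasons in
#' which the route was not surveyed at all are rows of `NA`, so `years` is
#' always a run of consecutive calendar years.
#'
#' @param route_id character or integer route identifier.
#' @param years strictly increasing, gap-free vector of calendar years.
#' @param obs integer matrix `[length(years) x n_stops]` with values in
#'   `{0, 1, NA}`.
#' @return An object of class `detection_history`.
#' @examples
#' h <- detection_history("r1", 2001:2003,
#'                        rbind(c(0, 1, 0), c(NA, NA, NA), c(0, 0, 1)))
#' h$n_stops
#' @export
detection_history <- function(route_id, years, obs) {
  obs <- as.matrix(obs)
  storage.mode(obs) <- "integer"
  if (length(years) < 1L) stop("a detection history needs at least one year")
  if (nrow(obs) != length(years)) {
    stop("'obs' must have one row per year")
  }
  if (is.unsorted(years, strictly = TRUE) ||
      (length(years) > 1L && any(diff(years) != 1L))) {
    stop("'years' must be strictly increasing consecutive calendar years ",
         "(represent unsurveyed years as all-NA rows)")
  }
  bad <- !(obs %in% c(0L, 1L, NA_integer_))
  if (any(bad)) {
    stop(sprintf("route '%s': observations must be 0, 1 or NA", route_id))
  }
  structure(
    list(route_id = as.character(route_id), years = as.integer(years),
         obs = obs, n_stops = ncol(obs)),
    class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  cat(sprintf("<detection_history> route %s: %d years (%d-%d), %d stops, %.1f%% missing\n",
              x$route_id, length(x$years), min(x$years), max(x$years),
              x$n_stops, 100 * mean(is.na(x$obs))))
  invisible(x)
}

#' Collection of detection histories
#'
#' Bundles per-route [detection_history()] objects into a dataset.  All
#' routes must share the same year span and stop count (shorter routes are
#' represented by trailing `NA` stops, which the likelihood marginalizes out
#' exactly).
#'
#' @param histories list of `detection_history` objects.
#' @return An object of class `occu_data`.
#' @export
occu_data <- function(histories) {
  if (length(histories) < 1L) stop("need at least one route")
  stopifnot(all(vapply(histories, inherits, TRUE, "detection_history")))
  yrs <- histories[[1L]]$years
  S <- histories[[1L]]$n_stops
  for (h in histories) {
    if (!identical(h$years, yrs)) {
      stop("all routes must cover the same years (pad with all-NA rows)")
    }
    if (h$n_stops != S) {
      stop(sprintf("route '%s' has %d stops; expected %d (pad with NA stops)",
                   h$route_id, h$n_stops, S))
    }
  }
  ids <- vapply(histories, `[[`, "", "route_id")
  if (anyDuplicated(ids)) stop("duplicate route ids")
  structure(list(histories = histories, years = yrs, n_stops = S,
                 route_ids = ids),
            class = "occu_data")
}

#' @export
print.occu_data <- function(x, ...) {
  cat(sprintf("<occu_data> %d routes x %d years (%d-%d) x %d stops\n",
              length(x$histories), length(x$years), min(x$years),
              max(x$years), x$n_stops))
  invisible(x)
}

#' @export
length.occu_data <- function(x) length(x$histories)

# Stack an occu_data into the S x T x R integer array consumed by the
# compiled likelihood (NA kept as NA_INTEGER).
obs_array <- function(data) {
  S <- data$n_stops
  T <- length(data$years)
  R <- length(data$histories)
  arr <- array(NA_integer_, dim = c(S, T, R))
  for (r in seq_len(R)) arr[, , r] <- t(data$histories[[r]]$obs)
  arr
}

#' Read stop-level detection histories from CSV
#'
#' Expects one row per route-year with columns `route_id`, `year`, and
#' `stop_01 ... stop_NN` holding 0, 1 or `NA`.  Years missing between a
#' route's first and last surveyed year are filled in as unsurveyed (all-NA)
#' rows; all routes are aligned onto the union year span.
#'
#' @param path path to a CSV file.
#' @param quiet suppress the per-file summary message.
#' @return An [occu_data()] object.
#' @export
read_detections <- function(path, quiet = FALSE) {
  df <- read.csv(path, check.names = FALSE)
  stop_cols <- grep("^stop_[0-9]+$", names(df), value = TRUE)
  if (!all(c("route_id", "year") %in% names(df)) || length(stop_cols) == 0L) {
    stop("detection CSV must have columns route_id, year, stop_01...")
  }
  stop_cols <- stop_cols[order(as.integer(sub("stop_", "", stop_cols)))]
  vals <- as.matrix(df[stop_cols])
  bad <- which(matrix(!(vals %in% c(0, 1, NA)), nrow(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("invalid stop value at data row %d, column %s (must be 0, 1 or NA)",
                 bad[1L, 1L], stop_cols[bad[1L, 2L]]))
  }
  if (anyDuplicated(df[c("route_id", "year")])) {
    i <- anyDuplicated(df[c("route_id", "year")])
    stop(sprintf("duplicate route-year at data row %d (route %s, year %s)",
                 i, df$route_id[i], df$year[i]))
  }
  years <- seq(min(df$year), max(df$year))
  S <- length(stop_cols)
  histories <- lapply(split(seq_len(nrow(df)), df$route_id), function(idx) {
    obs <- matrix(NA_integer_, length(years), S)
    obs[match(df$year[idx], years), ] <- as.integer(vals[idx, , drop = FALSE])
    detection_history(df$route_id[idx[1L]], years, obs)
  })
  data <- occu_data(unname(histories[unique(as.character(df$route_id))]))
  if (!quiet) {
    message(sprintf("read %d routes x %d years x %d stops from %s (%.1f%% missing)",
                    length(data$histories), length(years), S, path,
                    100 * mean(is.na(obs_array(data)))))
  }
  data
}

#' Write detection histories to CSV
#'
#' Inverse of [read_detections()]: one row per surveyed route-year.
#' All-NA (unsurveyed) years are omitted and recovered on read.
#'
#' @param data an [occu_data()] object.
#' @param path output CSV path.
#' @export
write_detections <- function(data, path) {
  S <- data$n_stops
  stop_cols <- sprintf("stop_%02d", seq_len(S))
  rows <- lapply(data$histories, function(h) {
    surveyed <- rowSums(!is.na(h$obs)) > 0L
    if (!any(surveyed)) return(NULL)
    out <- data.frame(route_id = h$route_id, year = h$years[surveyed])
    out[stop_cols] <- h$obs[surveyed, , drop = FALSE]
    out
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}
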