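test_that("hourly interpolation hits its anchors", {
  expect_equal(interpolate_hourly(20, 20, 20), rep(20, 24))
  h <- interpolate_hourly(10, 30, 12, sunrise = 6, peak = 15, sunset = 20)
  expect_equal(h[16], 30)       # hour index 16 = 15:00, the peak
  expect_equal(h[7], 10)        # sunrise
  # monotone nondecreasing rise from sunrise to peak
  expect_true(all(diff(h[7:16]) >= 0))
  # agreement with dense sampling of the defining sine segment
  dense <- 10 + 20 * sin(pi / 2 * ((6:15) - 6) / 9)
  expect_equal(h[7:16], dense, tolerance = 1e-12)
  # overnight decay heads toward the next-day minimum
  expect_true(all(diff(h[21:24]) < 0))
  expect_error(interpolate_hourly(31, 30, 12), "tmin")
})

test_that("hourly series chains days without gaps", {
  daily <- data.frame(date = as.Date("2013-06-01") + 0:9,
                      tmin_c = 15, tmax_c = 25)
  out <- interpolate_hourly_series(daily)
  expect_equal(nrow(out), 240)
  expect_true(all(out$temp_c >= 15 - 1e-9 & out$temp_c <= 25 + 1e-9))
  gap <- daily[-5, ]
  expect_error(interpolate_hourly_series(gap), "gap")
})

test_that("stress hours count strict threshold crossings per cycle", {
  expect_equal(stress_hours(constant_cycle_hourly(20))[, c("heat_hours", "cold_hours")],
               data.frame(heat_hours = 0, cold_hours = 0))
  expect_equal(stress_hours(constant_cycle_hourly(10))$cold_hours, 8760)
  expect_equal(stress_hours(constant_cycle_hourly(10))$heat_hours, 0)
  expect_equal(stress_hours(constant_cycle_hourly(40))$heat_hours, 8760)
  # cycle labeled by its ending calendar year
  expect_equal(stress_hours(constant_cycle_hourly(20))$year, 2014)
  # boundary values are not stress (strict inequalities)
  expect_equal(stress_hours(constant_cycle_hourly(18))$cold_hours, 0)
  expect_equal(stress_hours(constant_cycle_hourly(38))$heat_hours, 0)
  incomplete <- constant_cycle_hourly(20)[-1, ]
  expect_error(stress_hours(incomplete), "incomplete")
})

test_that("stress hours are monotone in temperature", {
  set.seed(1)
  base <- constant_cycle_hourly(20)
  base$temp_c <- rnorm(nrow(base), 20, 15)
  warmer <- base
  warmer$temp_c <- base$temp_c + runif(nrow(base), 0, 3)
  a <- stress_hours(base); b <- stress_hours(warmer)
  expect_gte(b$heat_hours, a$heat_hours)
  expect_lte(b$cold_hours, a$cold_hours)
})

test_that("trailing moving average", {
  expect_equal(moving_average(rep(3, 20), 15), rep(3, 6))
  expect_equal(moving_average(1:15, 15), 8)
  # linear trend: same slope out, lagged by (window - 1) / 2
  x <- 2 * (1:30) + 5
  out <- moving_average(x, 15)
  expect_equal(diff(out), rep(2, 15))
  expect_equal(out[1], mean(x[1:15]))
  # label carried from the window's ending year
  named <- setNames(1:20, 1981:2000)
  expect_equal(names(moving_average(named, 15)),
               as.character(1995:2000))
  expect_error(moving_average(1:10, 15), "shorter")
  # commutes with adding a constant
  expect_equal(moving_average(x + 7, 15), moving_average(x, 15) + 7)
})

test_that("land-cover snapshots map onto study years", {
  s <- assign_landcover_years(0.4, 0.3, 0.2)
  expect_equal(unname(s[as.character(1997:2001)]), rep(0.4, 5))
  expect_equal(unname(s[as.character(2002:2006)]), rep(0.3, 5))
  expect_equal(unname(s[as.character(2007:2012)]), rep(0.2, 6))
  expect_equal(unname(s[["2002"]]), 0.3) # 2002 takes the 2006 snapshot
  expect_equal(unname(assign_landcover_years(0.5, 0.5, 0.5)), rep(0.5, 16))
})

test_that("standardize uses the population-sd convention and replays", {
  z <- standardize(c(0, 2))
  expect_equal(as.vector(z), c(-1, 1))
  x <- rnorm(50, 3, 2)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-12)
  # idempotent when replayed with stored parameters
  z2 <- standardize(as.vector(z), center = 0, scale = 1)
  expect_equal(as.vector(z2), as.vector(z), tolerance = 1e-12)
  expect_error(standardize(rep(4, 5)), "zero-variance")
})

test_that("mean/deviation decomposition reconstructs exactly", {
  df <- data.frame(route_id = rep(c("a", "b"), each = 2),
                   year = rep(1:2, 2), value = c(1, 3, 10, 10))
  d <- decompose_covariate(df)
  expect_equal(d$mean[1:2], c(2, 2))
  expect_equal(d$dev[1:2], c(-1, 1))
  expect_equal(d$dev[3:4], c(0, 0))
  set.seed(2)
  df <- data.frame(route_id = rep(letters[1:6], each = 8),
                   year = rep(1:8, 6), value = rnorm(48))
  d <- decompose_covariate(df)
  expect_equal(d$mean + d$dev, df$value, tolerance = 1e-12)
  per_route <- tapply(d$dev, df$route_id, mean)
  expect_true(all(abs(per_route) < 1e-10))
})

test_that("prepare_covariates exposes both orders, affinely related", {
  set.seed(3)
  raw <- expand.grid(route_id = sprintf("r%02d", 1:8), year = 2001:2008,
                     stringsAsFactors = FALSE)
  raw$habitat <- runif(64, 0.2, 0.6)
  raw$heat <- rnorm(64, 2, 1)
  raw$cold <- rnorm(64, 5000, 300)
  a <- prepare_covariates(raw)
  expect_equal(mean(a$habitat_z), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(a$habitat_z^2)), 1, tolerance = 1e-10)
  expect_true(all(abs(tapply(a$cold_dev, a$route_id, mean)) < 1e-10))
  b <- prepare_covariates(raw, order = "decompose_first")
  # the two orders agree up to an affine map of each component
  expect_equal(abs(cor(a$heat_mean, b$heat_mean)), 1, tolerance = 1e-10)
  expect_equal(abs(cor(a$heat_dev, b$heat_dev)), 1, tolerance = 1e-10)
})

test_that("build_route_covariates runs the full chain", {
  des <- simulation_design(seed = 4)
  # 17 cycles of daily data -> 3 smoothed years with a 15-cycle window
  daily <- generate_daily_temperature(
    des, n_routes = 2,
    dates = seq(as.Date("1996-06-01"), as.Date("2013-05-31"), by = "day"))
  lc <- data.frame(route_id = unique(daily$route_id),
                   frac_2001 = c(0.4, 0.5), frac_2006 = c(0.35, 0.5),
                   frac_2011 = c(0.3, 0.5))
  tab <- build_route_covariates(daily, lc, years = 2011:2013,
                                prepare = FALSE)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$habitat[tab$route_id == "r0001"], rep(0.3, 3))
  expect_true(all(tab$cold > 0))
  expect_true(all(tab$heat >= 0))
  # cold stress declines toward the equator-end route (higher u is cooler)
  expect_error(build_route_covariates(daily, lc, years = 1997:2012),
               "does not cover")
})
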