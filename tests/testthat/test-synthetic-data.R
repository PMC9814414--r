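test_that("noise-free generator reproduces the smooth seasonal mean curve", {
  sc <- quiet_scenario(diurnal_amplitude = 0)
  s <- simulate_hourly_temperatures(sc, 2015, seed = 1)
  expected <- sc$peak_mean * exp(-0.5 * ((s$doy - sc$peak_doy) /
                                           sc$half_width)^2)
  expect_equal(s$temp_c, expected, tolerance = 1e-12)
  expect_true(all(s$flag == "observed"))
  expect_equal(nrow(s), 24 * (sc$season_end - sc$season_start + 1))
})

test_that("pure diurnal sinusoid spans twice its amplitude each day", {
  s <- simulate_hourly_temperatures(quiet_scenario(diurnal_amplitude = 4),
                                    2015, seed = 1)
  d <- daily_summaries(s)
  expect_equal(d$t_max - d$t_min, rep(8, nrow(d)), tolerance = 1e-12)
})

test_that("identical seed and parameters give bitwise-identical output", {
  sc <- scenario_high_arctic()
  expect_identical(simulate_hourly_temperatures(sc, 2015, seed = 7),
                   simulate_hourly_temperatures(sc, 2015, seed = 7))
  expect_identical(simulate_snowmelt(sc, 3, seed = 5),
                   simulate_snowmelt(sc, 3, seed = 5))
  sp <- default_species_set()[[1]]
  fr <- accumulate_forcing(simulate_hourly_temperatures(sc, 2015, seed = 7),
                           163, tmax_threshold = 5)
  expect_identical(simulate_censuses(fr, sp, 5, seed = 11),
                   simulate_censuses(fr, sp, 5, seed = 11))
})

test_that("invalid scenario parameters raise errors naming the invariant", {
  sc <- quiet_scenario()
  bad <- function(field, value) {
    s <- unclass(sc); s[[field]] <- value
    do.call(climate_scenario,
            s[setdiff(names(s), character(0))])
  }
  expect_error(bad("diurnal_amplitude", -1), "diurnal_amplitude")
  expect_error(bad("noise_sd", -0.1), "noise_sd")
  expect_error(bad("ar1_coefficient", 1), "ar1_coefficient")
  expect_error(bad("snowmelt_mean_doy", 10), "snowmelt_mean_doy")
})

test_that("zero warming deltas leave the series unchanged", {
  s <- simulate_hourly_temperatures(scenario_high_arctic(), 2015, seed = 3)
  w <- apply_warming(s, warming_spec(0, 0, 0))
  expect_equal(w$temp_c, s$temp_c, tolerance = 1e-12)
})

test_that("warming adds exactly the nighttime delta when the sun is down", {
  s <- simulate_hourly_temperatures(scenario_high_arctic(), 2015, seed = 3)
  w <- apply_warming(s, warming_spec(3, 0.4, 0.5))
  night <- cos(2 * pi * (s$hour - 15) / 24) <= 0
  expect_equal(w$temp_c[night] - s$temp_c[night],
               rep(0.4, sum(night)), tolerance = 1e-12)
})

test_that("daytime-only warming raises daily max more than daily mean", {
  # noise-free so every single day can be checked, per the sinusoidal-delta
  # evaluation: the bump raises the max by ~3 and the mean by ~3/pi
  s <- simulate_hourly_temperatures(quiet_scenario(diurnal_amplitude = 3),
                                    2015, seed = 1)
  w <- apply_warming(s, warming_spec(3, 0, 0))
  eff <- warming_effect(daily_summaries(s), daily_summaries(w))
  expect_true(all(eff$d_max > eff$d_mean))
  expect_true(all(eff$d_mean > eff$d_min))
  expect_equal(max(eff$d_max), 3, tolerance = 1e-6)
})

test_that("snowmelt simulation honours degenerate and shifted cases", {
  sc <- quiet_scenario()
  m0 <- simulate_snowmelt(sc, 0, seed = 1)
  expect_equal(m0$melt_doy, rep(sc$snowmelt_mean_doy, 2))
  m2 <- simulate_snowmelt(sc, 2, seed = 1)
  expect_equal(m2$melt_doy[m2$treatment == "warmed"],
               m2$melt_doy[m2$treatment == "ambient"] - 2)
})

test_that("snowmelt draws match the stated normal distribution", {
  sc <- quiet_scenario()
  sc$snowmelt_sd <- 3
  set.seed(10)
  seeds <- sample.int(1e6, 1000)
  draws <- vapply(seeds, function(s)
    simulate_snowmelt(sc, 0, seed = s)$melt_doy[1], 0)
  expect_gt(sd(draws), 2.5)
  expect_lt(sd(draws), 3.5)
  expect_lt(abs(mean(draws) - sc$snowmelt_mean_doy), 0.5)
})

test_that("a cold season with unreachable requirements yields all-zero counts", {
  sc <- quiet_scenario(peak_mean = 1)
  s <- simulate_hourly_temperatures(sc, 2015, seed = 1)
  fr <- accumulate_forcing(s, sc$snowmelt_mean_doy, tmax_threshold = 5)
  sp <- species_response("sp", 5, mean_thermal_requirement = 1e5,
                         requirement_cv = 0.1, buds_per_plot_mean = 4)
  sim <- simulate_censuses(fr, sp, 6, seed = 2)
  expect_true(all(sim$censuses$n_open == 0))
  expect_true(all(sim$censuses$n_senesced == 0))
  expect_true(all(is.na(sim$truth$open_doy)))
})

test_that("a degenerate requirement distribution flowers at a single census", {
  sc <- quiet_scenario(peak_mean = 8, season_end = 200)
  s <- simulate_hourly_temperatures(sc, 2015, seed = 1)
  fr <- accumulate_forcing(s, sc$snowmelt_mean_doy, tmax_threshold = 5)
  sp <- species_response("sp", 5, mean_thermal_requirement = 50,
                         requirement_cv = 1e-9, buds_per_plot_mean = 1,
                         senescence_duration = 1)
  sim <- simulate_censuses(fr, sp, 20, seed = 2)
  withflowers <- sim$censuses[sim$censuses$n_open > 0, ]
  expect_lte(length(unique(withflowers$census_doy)), 1)
  # crossing can straddle a midnight boundary at machine precision, so the
  # true opening dates agree to within a day
  expect_lte(diff(range(sim$truth$open_doy)), 1)
})

test_that("final senesced counts match opening dates in the truth table", {
  sc <- quiet_scenario(peak_mean = 8, season_end = 220)
  s <- simulate_hourly_temperatures(sc, 2015, seed = 4)
  fr <- accumulate_forcing(s, sc$snowmelt_mean_doy, tmax_threshold = 5)
  sp <- species_response("sp", 5, mean_thermal_requirement = 60,
                         requirement_cv = 0.3, buds_per_plot_mean = 5,
                         senescence_duration = 4)
  sim <- simulate_censuses(fr, sp, 8, seed = 9)
  last <- max(sim$censuses$census_doy)
  final <- sim$censuses[sim$censuses$census_doy == last, ]
  expected <- sum(!is.na(sim$truth$open_doy) &
                    sim$truth$open_doy + sp$senescence_duration <= last)
  expect_equal(sum(final$n_senesced), expected)
})

test_that("census bookkeeping is internally consistent per plot", {
  sc <- quiet_scenario(peak_mean = 8, season_end = 220)
  s <- simulate_hourly_temperatures(sc, 2015, seed = 4)
  fr <- accumulate_forcing(s, sc$snowmelt_mean_doy, tmax_threshold = 5)
  sp <- species_response("sp", 5, mean_thermal_requirement = 60,
                         requirement_cv = 0.3, buds_per_plot_mean = 5,
                         senescence_duration = 4)
  sim <- simulate_censuses(fr, sp, 8, seed = 9)
  for (p in unique(sim$censuses$plot)) {
    g <- sim$censuses[sim$censuses$plot == p, ]
    tr <- sim$truth[sim$truth$plot == p, ]
    expect_true(all(diff(g$n_senesced) >= 0))
    opened_so_far <- vapply(g$census_doy, function(d)
      sum(!is.na(tr$open_doy) & tr$open_doy <= d), 0)
    expect_true(all(g$n_open + g$n_senesced <= opened_so_far))
  }
})

test_that("warming applies to censuses through earlier snowmelt and hotter days", {
  ds <- small_dataset(seed = 21, years = 2011:2013,
                      warming = warming_spec())
  expect_setequal(unique(ds$censuses$treatment), c("ambient", "warmed"))
  melt <- reshape(ds$snow, idvar = "year", timevar = "treatment",
                  direction = "wide")
  expect_true(all(melt$melt_doy.warmed <= melt$melt_doy.ambient))
})
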