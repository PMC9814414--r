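#' Define a seasonal climate scenario
#'
#' A climate scenario describes the statistical structure of a location's
#' snow-free season: a smooth Gaussian-bump seasonal mean temperature curve, a
#' diurnal sinusoid peaking mid-afternoon, stationary AR(1) hourly noise, a
#' per-year mean anomaly, and the distribution of snowmelt dates. Two presets
#' emulate a colder high-Arctic and a warmer low-Arctic tundra site.
#'
#' @param region_label Character label for the location.
#' @param season_start,season_end First/last day-of-year of the simulated
#'   season.
#' @param peak_mean Seasonal peak of the daily mean temperature curve (deg C).
#' @param peak_doy Day-of-year at which the seasonal mean curve peaks.
#' @param half_width Gaussian half-width of the seasonal curve (days).
#' @param diurnal_amplitude Amplitude of the diurnal sinusoid (deg C); the
#'   daily range of the noise-free series is twice this value.
#' @param ar1_coefficient AR(1) coefficient of the hourly noise, in [0, 1).
#' @param noise_sd Innovation standard deviation of the AR(1) noise (deg C).
#' @param snowmelt_mean_doy,snowmelt_sd Mean and SD (days) of the annual
#'   snowmelt date.
#' @param year_anomaly_sd SD (deg C) of a constant per-year temperature
#'   anomaly added to the seasonal mean curve; emulates warm and cold summers.
#' @return An object of class `climate_scenario`.
#' @seealso [simulate_hourly_temperatures()], [simulate_snowmelt()]
#' @export
climate_scenario <- function(region_label, season_start, season_end,
                             peak_mean, peak_doy, half_width,
                             diurnal_amplitude, ar1_coefficient, noise_sd,
                             snowmelt_mean_doy, snowmelt_sd,
                             year_anomaly_sd = 0) {
  sc <- list(region_label = region_label,
             season_start = as.integer(season_start),
             season_end = as.integer(season_end),
             peak_mean = peak_mean, peak_doy = peak_doy,
             half_width = half_width,
             diurnal_amplitude = diurnal_amplitude,
             ar1_coefficient = ar1_coefficient, noise_sd = noise_sd,
             snowmelt_mean_doy = snowmelt_mean_doy,
             snowmelt_sd = snowmelt_sd,
             year_anomaly_sd = year_anomaly_sd)
  validate_scenario(sc)
  structure(sc, class = "climate_scenario")
}

validate_scenario <- function(sc) {
  if (sc$diurnal_amplitude < 0)
    stop("invalid scenario: diurnal_amplitude must be >= 0", call. = FALSE)
  if (sc$noise_sd < 0)
    stop("invalid scenario: noise_sd must be >= 0", call. = FALSE)
  if (sc$ar1_coefficient < 0 || sc$ar1_coefficient >= 1)
    stop("invalid scenario: ar1_coefficient must be in [0, 1)", call. = FALSE)
  if (!(sc$season_start < sc$snowmelt_mean_doy &&
        sc$snowmelt_mean_doy < sc$season_end))
    stop("invalid scenario: season_start < snowmelt_mean_doy < season_end ",
         "is required", call. = FALSE)
  if (sc$snowmelt_sd < 0)
    stop("invalid scenario: snowmelt_sd must be >= 0", call. = FALSE)
  if (sc$year_anomaly_sd < 0)
    stop("invalid scenario: year_anomaly_sd must be >= 0", call. = FALSE)
  if (sc$half_width <= 0)
    stop("invalid scenario: half_width must be > 0", call. = FALSE)
  invisible(sc)
}

#' @rdname climate_scenario
#' @export
scenario_high_arctic <- function() {
  climate_scenario("high_arctic", season_start = 152, season_end = 273,
                   peak_mean = 6, peak_doy = 200, half_width = 40,
                   diurnal_amplitude = 3, ar1_coefficient = 0.8,
                   noise_sd = 1.5, snowmelt_mean_doy = 163, snowmelt_sd = 5,
                   year_anomaly_sd = 0.7)
}

#' @rdname climate_scenario
#' @export
scenario_low_arctic <- function() {
  climate_scenario("low_arctic", season_start = 145, season_end = 273,
                   peak_mean = 11, peak_doy = 198, half_width = 40,
                   diurnal_amplitude = 4.5, ar1_coefficient = 0.8,
                   noise_sd = 1.8, snowmelt_mean_doy = 156, snowmelt_sd = 5,
                   year_anomaly_sd = 0.8)
}

#' Define a passive-warming treatment effect
#'
#' Open-top chambers warm mainly when the sun is up: the added temperature
#' delta follows a solar proxy (the diurnal sinusoid clipped at zero at
#' night), so daily maxima increase more than daily means while nighttime
#' minima change by only `nighttime_delta`. The daytime component shrinks
#' linearly across the season by `seasonal_decay` to emulate waning solar
#' input.
#'
#' @param peak_daytime_delta Delta (deg C) added at the solar-noon maximum in
#'   early season.
#' @param nighttime_delta Delta (deg C) at night; near zero for passive
#'   chambers.
#' @param seasonal_decay Fraction in [0, 1] by which the daytime delta has
#'   shrunk at season end relative to season start.
#' @return An object of class `warming_spec`.
#' @export
warming_spec <- function(peak_daytime_delta = 3, nighttime_delta = 0.3,
                         seasonal_decay = 0.5) {
  if (!(peak_daytime_delta >= nighttime_delta && nighttime_delta >= 0))
    stop("invalid warming spec: peak_daytime_delta >= nighttime_delta >= 0 ",
         "is required", call. = FALSE)
  if (seasonal_decay < 0 || seasonal_decay > 1)
    stop("invalid warming spec: seasonal_decay must be in [0, 1]",
         call. = FALSE)
  structure(list(peak_daytime_delta = peak_daytime_delta,
                 nighttime_delta = nighttime_delta,
                 seasonal_decay = seasonal_decay), class = "warming_spec")
}

#' Define a species' thermal flowering response
#'
#' Each bud carries a thermal-time requirement (lognormal, strictly positive)
#' expressed in degree-days of capped forcing: the bud opens on the first day
#' that cumulative forcing, computed with the species' own `true_tmax` cap,
#' reaches its requirement. `true_tmax = NA` defines a linear (uncapped)
#' responder whose requirement is in plain GDD.
#'
#' @param name Species label (sex-/subspecies-qualified names are treated as
#'   distinct species).
#' @param true_tmax True maximum-temperature cap (deg C) of the generative
#'   response, or `NA` for an uncapped linear responder.
#' @param mean_thermal_requirement Mean degree-days to flower opening.
#' @param requirement_cv Coefficient of variation of the requirement.
#' @param buds_per_plot_mean Poisson mean number of buds per plot.
#' @param senescence_duration Days a flower remains countable as
#'   non-senesced after opening.
#' @return An object of class `species_response`.
#' @export
species_response <- function(name, true_tmax, mean_thermal_requirement,
                             requirement_cv, buds_per_plot_mean,
                             senescence_duration = 7) {
  if (!is.na(true_tmax) && true_tmax <= 0)
    stop("invalid species response: true_tmax must be > 0 when present",
         call. = FALSE)
  if (mean_thermal_requirement <= 0)
    stop("invalid species response: mean_thermal_requirement must be > 0",
         call. = FALSE)
  if (requirement_cv <= 0)
    stop("invalid species response: requirement_cv must be > 0",
         call. = FALSE)
  if (buds_per_plot_mean <= 0)
    stop("invalid species response: buds_per_plot_mean must be > 0",
         call. = FALSE)
  if (senescence_duration < 1)
    stop("invalid species response: senescence_duration must be >= 1",
         call. = FALSE)
  structure(list(name = name, true_tmax = true_tmax,
                 mean_thermal_requirement = mean_thermal_requirement,
                 requirement_cv = requirement_cv,
                 buds_per_plot_mean = buds_per_plot_mean,
                 senescence_duration = senescence_duration),
            class = "species_response")
}

#' Default synthetic species set
#'
#' One saturating responder with a 5 deg C cap and one linear (uncapped)
#' responder, with requirements placed so flowering peaks mid-season under
#' the high-Arctic scenario.
#'
#' @return A list of [species_response()] objects.
#' @export
default_species_set <- function() {
  list(species_response("capped_responder", true_tmax = 5,
                        mean_thermal_requirement = 70, requirement_cv = 0.25,
                        buds_per_plot_mean = 6, senescence_duration = 1),
       species_response("linear_responder", true_tmax = NA,
                        mean_thermal_requirement = 130, requirement_cv = 0.25,
                        buds_per_plot_mean = 6, senescence_duration = 1))
}

#' Simulate one season of hourly canopy temperatures
#'
#' Temperature = seasonal Gaussian mean curve + per-year anomaly + diurnal
#' sinusoid (peak at 15:00 local) + stationary AR(1) noise. One record per
#' hour from `season_start` to `season_end`, all flagged `"observed"`.
#'
#' @param scenario A [climate_scenario()].
#' @param year Calendar year (used for timestamps and grouping only).
#' @param seed Integer seed; identical seed and parameters give a bitwise
#'   identical series.
#' @return A data frame with columns `location`, `treatment`, `year`, `doy`,
#'   `hour`, `time` (fractional day-of-year), `temp_c`, `flag`.
#' @export
simulate_hourly_temperatures <- function(scenario, year, seed = NULL) {
  validate_scenario(scenario)
  if (!is.null(seed)) set.seed(seed)
  doy <- seq(scenario$season_start, scenario$season_end)
  hour <- 0:23
  g <- expand.grid(hour = hour, doy = doy)
  n <- nrow(g)
  anom <- if (scenario$year_anomaly_sd > 0)
    stats::rnorm(1, 0, scenario$year_anomaly_sd) else 0
  seasonal <- scenario$peak_mean *
    exp(-0.5 * ((g$doy - scenario$peak_doy) / scenario$half_width)^2)
  diurnal <- scenario$diurnal_amplitude * cos(2 * pi * (g$hour - 15) / 24)
  noise <- if (scenario$noise_sd > 0) {
    phi <- scenario$ar1_coefficient
    x0 <- stats::rnorm(1, 0, scenario$noise_sd / sqrt(1 - phi^2))
    e <- stats::rnorm(n, 0, scenario$noise_sd)
    as.numeric(stats::filter(e, phi, method = "recursive", init = x0))
  } else rep(0, n)
  data.frame(location = scenario$region_label, treatment = "ambient",
             year = as.integer(year), doy = g$doy, hour = g$hour,
             time = g$doy + g$hour / 24,
             temp_c = seasonal + anom + diurnal + noise,
             flag = "observed", stringsAsFactors = FALSE)
}

#' Apply a passive-warming treatment to an hourly series
#'
#' Adds `nighttime_delta` plus a daytime bump proportional to the solar proxy
#' `max(0, cos(2 pi (hour - 15) / 24))`, scaled down linearly across the
#' season by `seasonal_decay`. At night (solar proxy zero) the added delta is
#' exactly `nighttime_delta`; over full days the increase in the daily
#' maximum exceeds the increase in the daily mean, which exceeds the increase
#' in the daily minimum.
#'
#' @param series Hourly temperature series as returned by
#'   [simulate_hourly_temperatures()] (complete hourly grid).
#' @param spec A [warming_spec()].
#' @return The warmed series, with `treatment = "warmed"`.
#' @export
apply_warming <- function(series, spec) {
  stopifnot(inherits(spec, "warming_spec"))
  validate_hourly(series)
  solar <- pmax(0, cos(2 * pi * (series$hour - 15) / 24))
  span <- range(series$doy)
  frac <- if (span[2] > span[1])
    (series$doy - span[1]) / (span[2] - span[1]) else 0
  fac <- 1 - spec$seasonal_decay * frac
  delta <- spec$nighttime_delta +
    (spec$peak_daytime_delta - spec$nighttime_delta) * solar * fac
  out <- series
  out$temp_c <- series$temp_c + delta
  out$treatment <- "warmed"
  out
}

#' Simulate snowmelt dates for both treatments
#'
#' Ambient snowmelt is drawn from Normal(`snowmelt_mean_doy`, `snowmelt_sd`)
#' and rounded to a day; warmed-plot snowmelt is `warming_advance_days`
#' earlier. Both are floored at `season_start`.
#'
#' @param scenario A [climate_scenario()].
#' @param warming_advance_days Days by which passive warming advances
#'   snowmelt (>= 0).
#' @param seed Integer seed.
#' @return Data frame with columns `treatment`, `melt_doy`.
#' @export
simulate_snowmelt <- function(scenario, warming_advance_days = 3,
                              seed = NULL) {
  validate_scenario(scenario)
  if (warming_advance_days < 0)
    stop("warming_advance_days must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  amb <- round(stats::rnorm(1, scenario$snowmelt_mean_doy,
                            scenario$snowmelt_sd))
  amb <- max(amb, scenario$season_start)
  wrm <- max(amb - warming_advance_days, scenario$season_start)
  data.frame(treatment = c("ambient", "warmed"),
             melt_doy = as.numeric(c(amb, wrm)), stringsAsFactors = FALSE)
}

#' Simulate plot-level flower censuses from a forcing series
#'
#' Per plot, the bud count is Poisson(`buds_per_plot_mean`); each bud's
#' thermal requirement is lognormal with mean `mean_thermal_requirement` and
#' CV `requirement_cv`, and the bud opens on the first day cumulative forcing
#' reaches its requirement. A flower is counted non-senesced at censuses
#' within `senescence_duration` days of opening, and senesced thereafter.
#' Censuses run every `census_interval` days from just before snowmelt to the
#' end of the forcing span, optionally jittered by up to `jitter_days`.
#'
#' @param forcing A [forcing_series] computed with the species' own true cap
#'   (or uncapped for a linear responder).
#' @param response A [species_response()].
#' @param n_plots Number of plots (>= 1).
#' @param census_interval Nominal days between censuses.
#' @param seed Integer seed.
#' @param jitter_days Maximum census-date jitter in days (0, 1 or 2);
#'   `census_interval - 2 * jitter_days` must stay positive.
#' @return A list with elements `censuses` (species, plot, location,
#'   treatment, census_doy, n_open, n_senesced) and `truth` (plot, bud_id,
#'   requirement_dd, open_doy; `NA` open date if the requirement is never
#'   reached).
#' @export
simulate_censuses <- function(forcing, response, n_plots,
                              census_interval = 7, seed = NULL,
                              jitter_days = 0) {
  stopifnot(inherits(forcing, "forcing_series"),
            inherits(response, "species_response"))
  if (n_plots < 1) stop("n_plots must be >= 1", call. = FALSE)
  if (!jitter_days %in% 0:2)
    stop("jitter_days must be 0, 1 or 2", call. = FALSE)
  if (census_interval - 2 * jitter_days < 1)
    stop("census_interval too short for the requested jitter", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  span <- range(forcing$time)
  if (span[2] - span[1] < census_interval)
    stop("forcing series does not cover a full census interval",
         call. = FALSE)
  first <- max(floor(span[1]), forcing$snowmelt_doy - census_interval)
  dates <- seq(first, floor(span[2]), by = census_interval)
  if (jitter_days > 0 && length(dates) > 2) {
    mid <- seq(2, length(dates) - 1)
    dates[mid] <- dates[mid] + sample(seq(-jitter_days, jitter_days),
                                      length(mid), replace = TRUE)
  }
  dates <- dates[dates >= span[1] & dates <= span[2]]

  lp <- lognormal_params(response$mean_thermal_requirement,
                         response$requirement_cv)
  truth <- list()
  cens <- list()
  for (p in seq_len(n_plots)) {
    nb <- stats::rpois(1, response$buds_per_plot_mean)
    req <- if (nb > 0) stats::rlnorm(nb, lp$meanlog, lp$sdlog) else numeric(0)
    open_doy <- rep(NA_real_, nb)
    if (nb > 0) {
      pos <- findInterval(req, forcing$cumulative, left.open = TRUE) + 1L
      ok <- pos <= length(forcing$cumulative)
      open_doy[ok] <- floor(forcing$time[pos[ok]])
    }
    truth[[p]] <- if (nb > 0)
      data.frame(species = response$name, plot = p, bud_id = seq_len(nb),
                 requirement_dd = req, open_doy = open_doy,
                 stringsAsFactors = FALSE) else NULL
    opened <- open_doy[!is.na(open_doy)]
    n_open <- vapply(dates, function(d)
      sum(opened <= d & d < opened + response$senescence_duration), 0)
    n_sen <- vapply(dates, function(d)
      sum(d >= opened + response$senescence_duration), 0)
    cens[[p]] <- data.frame(species = response$name, plot = p,
                            location = forcing$location,
                            treatment = forcing$treatment,
                            census_doy = dates,
                            n_open = as.integer(n_open),
                            n_senesced = as.integer(n_sen),
                            stringsAsFactors = FALSE)
  }
  list(censuses = do.call(rbind, cens), truth = do.call(rbind, truth))
}

#' Simulate a complete multi-year phenology dataset
#'
#' Runs the full generative model: hourly ambient temperatures per year, the
#' passive-warming treatment, snowmelt dates per treatment, and plot-level
#' flower censuses for every species under the forcing implied by its own
#' true response. All randomness derives from one master seed.
#'
#' @param scenario A [climate_scenario()].
#' @param warming A [warming_spec()], or `NULL` to simulate ambient plots
#'   only.
#' @param species A list of [species_response()] objects.
#' @param years Vector of calendar years to simulate.
#' @param n_plots Plots per treatment.
#' @param census_interval Days between censuses.
#' @param warming_advance_days Snowmelt advance in warmed plots.
#' @param jitter_days Census-date jitter passed to [simulate_censuses()].
#' @param seed Master seed.
#' @return A list with data frames `temps` (hourly, all treatments and
#'   years), `snow` (treatment, year, melt_doy), `censuses`, `truth`, plus
#'   the generator inputs (`scenario`, `warming`, `species`, `seed`).
#' @export
simulate_phenology_dataset <- function(scenario, warming = warming_spec(),
                                       species = default_species_set(),
                                       years = 2011:2018, n_plots = 24,
                                       census_interval = 7,
                                       warming_advance_days = 3,
                                       jitter_days = 0, seed = 1) {
  treatments <- if (is.null(warming)) "ambient" else c("ambient", "warmed")
  temps <- list(); snow <- list(); cens <- list(); truth <- list()
  for (y in years) {
    amb <- simulate_hourly_temperatures(scenario, y,
                                        derive_seed(seed, paste0("temps", y)))
    sm <- simulate_snowmelt(scenario, warming_advance_days,
                            derive_seed(seed, paste0("snow", y)))
    sm$year <- as.integer(y)
    snow[[as.character(y)]] <- sm[sm$treatment %in% treatments, ]
    series <- list(ambient = amb)
    if (!is.null(warming)) series$warmed <- apply_warming(amb, warming)
    temps[[as.character(y)]] <- do.call(rbind, series)
    for (tr in treatments) {
      melt <- sm$melt_doy[sm$treatment == tr]
      for (sp in species) {
        cap <- if (is.na(sp$true_tmax)) NULL else sp$true_tmax
        fr <- accumulate_forcing(series[[tr]], melt, tmax_threshold = cap)
        sim <- simulate_censuses(fr, sp, n_plots, census_interval,
                                 seed = derive_seed(
                                   seed, paste("census", y, tr, sp$name)),
                                 jitter_days = jitter_days)
        sim$censuses$year <- as.integer(y)
        sim$truth$year <- as.integer(y)
        sim$truth$treatment <- tr
        sim$truth$location <- scenario$region_label
        key <- paste(y, tr, sp$name)
        cens[[key]] <- sim$censuses
        truth[[key]] <- sim$truth
      }
    }
  }
  list(temps = do.call(rbind, c(temps, list(make.row.names = FALSE))),
       snow = do.call(rbind, c(snow, list(make.row.names = FALSE))),
       censuses = do.call(rbind, c(cens, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       scenario = scenario, warming = warming, species = species,
       seed = seed)
}

#' First-flowering dates implied by generator truth
#'
#' The earliest true opening date per species x location x treatment x year,
#' standing in for the early-season first-flowering survey used to anchor
#' series whose first census already contains flowers.
#'
#' @param truth The `truth` table of [simulate_phenology_dataset()] or
#'   [simulate_censuses()].
#' @return Data frame with columns `species`, `location`, `treatment`,
#'   `year`, `first_flower_doy`.
#' @export
first_flower_from_truth <- function(truth) {
  keys <- intersect(c("species", "location", "treatment", "year"),
                    names(truth))
  ok <- !is.na(truth$open_doy)
  if (!any(ok)) return(NULL)
  agg <- stats::aggregate(truth$open_doy[ok],
                          by = truth[ok, keys, drop = FALSE], FUN = min)
  names(agg)[ncol(agg)] <- "first_flower_doy"
  agg
}
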