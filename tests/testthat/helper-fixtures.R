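# Fixture builders shared across test files. Everything is generated in code;
# no data files are read.

# an hourly series from an explicit temperature vector (NA = missing hour)
make_hourly <- function(temps, start_doy = 150, year = 2015,
                        location = "test", treatment = "ambient") {
  n <- length(temps)
  doy <- start_doy + (seq_len(n) - 1) %/% 24
  hour <- (seq_len(n) - 1) %% 24
  data.frame(location = location, treatment = treatment, year = year,
             doy = doy, hour = hour, time = doy + hour / 24,
             temp_c = temps,
             flag = ifelse(is.na(temps), "missing", "observed"),
             stringsAsFactors = FALSE)
}

# a scenario with every stochastic component switched off
quiet_scenario <- function(diurnal_amplitude = 0, peak_mean = 6,
                           season_start = 150, season_end = 170,
                           snowmelt_mean_doy = 155) {
  climate_scenario("quiet", season_start = season_start,
                   season_end = season_end, peak_mean = peak_mean,
                   peak_doy = 160, half_width = 30,
                   diurnal_amplitude = diurnal_amplitude,
                   ar1_coefficient = 0, noise_sd = 0,
                   snowmelt_mean_doy = snowmelt_mean_doy, snowmelt_sd = 0,
                   year_anomaly_sd = 0)
}

# a small plot-level census table built directly from count vectors
make_census <- function(n_open, n_senesced, dates = NULL, plot = 1,
                        species = "sp", year = 2015) {
  if (is.null(dates)) dates <- seq(160, by = 7, length.out = length(n_open))
  data.frame(species = species, plot = plot, location = "test",
             treatment = "ambient", year = year, census_doy = dates,
             n_open = n_open, n_senesced = n_senesced,
             stringsAsFactors = FALSE)
}

# random valid plot census history: senesced counts non-decreasing
random_census <- function(n = 8, seed = 1, plot = 1) {
  set.seed(seed)
  make_census(n_open = rpois(n, 3),
              n_senesced = cumsum(rpois(n, 2)),
              plot = plot)
}

# small multi-year ambient dataset for model-level tests
small_dataset <- function(seed = 99, years = 2011:2016, sp = NULL,
                          warming = NULL) {
  sp <- sp %||% default_species_set()[[1]]
  simulate_phenology_dataset(scenario_high_arctic(), warming = warming,
                             species = list(sp), years = years, seed = seed)
}

ambient <- function(df) df[df$treatment == "ambient", ]
warmed <- function(df) df[df$treatment == "warmed", ]

`%||%` <- function(a, b) if (is.null(a)) b else a

# forcing list per year from a dataset, for one treatment
dataset_forcings <- function(ds, treat = "ambient", cap = NULL,
                             type = NULL) {
  temps <- ds$temps[ds$temps$treatment == treat, ]
  out <- lapply(split(temps, temps$year), function(s) {
    melt <- ds$snow$melt_doy[ds$snow$year == s$year[1] &
                               ds$snow$treatment == treat]
    accumulate_forcing(s, melt, tmax_threshold = cap, forcing_type = type)
  })
  stats::setNames(out, names(out))
}
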