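# Default configuration for phenocap::run_pipeline(). Any subset of these
# keys can be overridden; omitted keys keep the values shown here.
scenario: high_arctic          # or low_arctic, or a full parameter block
warming:
  peak_daytime_delta: 3.0      # degC added at the solar-noon maximum
  nighttime_delta: 0.3         # degC added at night
  seasonal_decay: 0.5          # daytime delta shrinks by this fraction
warming_advance_days: 3        # snowmelt advance in warmed plots
species:
  - name: capped_responder
    true_tmax: 5.0             # degC; generative maximum-temperature cap
    mean_thermal_requirement: 70.0   # degree-days to flower opening
    requirement_cv: 0.25
    buds_per_plot_mean: 6.0
    senescence_duration: 1     # days a flower stays non-senesced
  - name: linear_responder
    true_tmax: .na             # uncapped (linear) thermal response
    mean_thermal_requirement: 130.0
    requirement_cv: 0.25
    buds_per_plot_mean: 6.0
    senescence_duration: 1
years: [2011, 2012, 2013, 2014, 2015, 2016, 2017, 2018]
n_plots: 24
census_interval: 7             # days; ~weekly censuses
jitter_days: 0                 # optional +/- jitter of census dates
grid:                          # temperature-cap scan grid, degC
  from: 0.5
  to: 20.0
  by: 0.5
k: 10                          # spline basis dimension
delta_aic_rule: 2.0            # AIC margin for a saturating call
quantile: 0.95                 # summer temperature reference quantile
screening:
  min_years: 6                 # qualifying ambient years for inclusion
  min_total: 5                 # minimum seasonal total for a usable peak
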