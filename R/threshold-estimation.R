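#' Default temperature-cap scan grid
#'
#' 0.5 to 20.1 deg C in 0.2 deg steps. Coarser grids (e.g. 0.5 deg steps) cut
#' the refit count proportionally and are adequate when only the AIC-profile
#' minimum is needed.
#'
#' @param from,to,by Grid bounds and step in deg C.
#' @return Numeric vector of candidate caps.
#' @export
default_threshold_grid <- function(from = 0.5, to = 20.1, by = 0.2) {
  seq(from, to, by = by)
}

normalize_temps <- function(temps) {
  if (is.data.frame(temps)) {
    if (!"year" %in% names(temps))
      stop("a pooled temperature table needs a year column", call. = FALSE)
    temps <- lapply(split(temps, temps$year), validate_hourly)
  }
  stats::setNames(temps, vapply(temps, function(s)
    as.character(s$year[1]), ""))
}

normalize_snow <- function(snow) {
  if (is.data.frame(snow)) {
    if ("treatment" %in% names(snow) && any(snow$treatment == "ambient"))
      snow <- snow[snow$treatment == "ambient", ]
    stats::setNames(snow$melt_doy, as.character(snow$year))
  } else {
    if (is.null(names(snow)))
      stop("snowmelt vector must be named by year", call. = FALSE)
    snow
  }
}

# Precompute one design table per candidate cap (plus the uncapped
# reference). Forcing series are cached here so the jackknife refits reuse
# them instead of re-accumulating per left-out year.
threshold_designs <- function(flowers, temps, snow,
                              grid = default_threshold_grid()) {
  temps <- normalize_temps(temps)
  snow <- normalize_snow(snow)
  years <- sort(unique(flowers$year))
  miss <- setdiff(as.character(years), names(temps))
  if (length(miss))
    stop("no temperature series for year(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  one <- function(cap) {
    fr <- lapply(as.character(years), function(y)
      accumulate_forcing(temps[[y]], snow[[y]], tmax_threshold = cap))
    names(fr) <- as.character(years)
    build_design(flowers, fr)
  }
  list(grid = grid,
       designs = lapply(grid, one),
       uncapped = one(NULL))
}

fit_aic <- function(design, omit_year, k) {
  if (!is.null(omit_year))
    design <- design[!(as.character(design$year) %in%
                         as.character(omit_year)), , drop = FALSE]
  tryCatch(
    suppressWarnings(fit_phenology_gam(design, k = k)$aic),
    error = function(e) NA_real_)
}

#' Scan candidate temperature caps by AIC
#'
#' For each cap on the grid the forcing is recomputed, the seasonal count
#' model refit with an identical specification, and the ML AIC recorded,
#' together with the uncapped-GDD reference fit. The profile minimum is the
#' estimated cap; AIC ties break toward the lower cap. Non-converged grid
#' points are recorded as `NA`, never interpolated, and an isolated AIC spike
#' of more than 10 units relative to both neighbours raises an audit flag.
#'
#' @param flowers Ambient new-flower series (one species x location) with
#'   midpoints and intervals.
#' @param temps Ambient hourly series: a pooled data frame with a `year`
#'   column, or a list of per-year series.
#' @param snow Ambient snowmelt dates: data frame (`year`, `melt_doy`) or a
#'   year-named numeric vector.
#' @param grid Candidate caps in deg C, strictly ascending.
#' @param k Spline basis dimension.
#' @param omit_year Optional year(s) to leave out (used by the jackknife).
#' @param designs Precomputed [threshold_designs] cache (internal reuse).
#' @return An object of class `threshold_profile` with elements `grid`,
#'   `aic`, `aic_uncapped`, `best_threshold`, `delta_aic_vs_uncapped`,
#'   `omit_year` and `audit_flags`.
#' @export
scan_thresholds <- function(flowers, temps, snow,
                            grid = default_threshold_grid(), k = 10,
                            omit_year = NULL, designs = NULL) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly ascending", call. = FALSE)
  if (is.null(designs))
    designs <- threshold_designs(flowers, temps, snow, grid)
  aic <- vapply(designs$designs, fit_aic, 0, omit_year = omit_year, k = k)
  aic_unc <- fit_aic(designs$uncapped, omit_year, k)
  if (all(is.na(aic)))
    stop("no grid point produced a converged fit", call. = FALSE)
  best <- which.min(aic)
  spikes <- integer(0)
  if (length(aic) >= 3) {
    for (i in 2:(length(aic) - 1)) {
      trio <- aic[(i - 1):(i + 1)]
      if (!anyNA(trio) &&
          min(abs(trio[2] - trio[c(1, 3)])) > 10) spikes <- c(spikes, i)
    }
  }
  structure(list(grid = designs$grid, aic = aic, aic_uncapped = aic_unc,
                 best_threshold = designs$grid[best],
                 delta_aic_vs_uncapped = aic[best] - aic_unc,
                 omit_year = omit_year,
                 audit_flags = designs$grid[spikes]),
            class = "threshold_profile")
}

#' @export
print.threshold_profile <- function(x, ...) {
  cat(sprintf(
    "<threshold_profile> grid %.1f..%.1f degC (%d points)%s\n  best cap %.2f degC, AIC %.3f (uncapped %.3f, delta %.3f)\n",
    min(x$grid), max(x$grid), length(x$grid),
    if (is.null(x$omit_year)) "" else
      paste0(", omitting year ", paste(x$omit_year, collapse = ",")),
    x$best_threshold, min(x$aic, na.rm = TRUE), x$aic_uncapped,
    x$delta_aic_vs_uncapped))
  if (length(x$audit_flags))
    cat("  audit: AIC spikes at", paste(x$audit_flags, collapse = ", "),
        "degC\n")
  invisible(x)
}

#' Classify a saturating vs non-saturating response
#'
#' The response is called saturating when the capped model beats the uncapped
#' GDD model by at least `delta_aic_rule` AIC units AND the best cap lies
#' within the commonly observed temperature range (at or below `temp_q95`).
#' Both margins are returned for audit; the margin against the top of the
#' grid is reported as well.
#'
#' @param profile A `threshold_profile`.
#' @param temp_q95 Reference quantile of observed snow-free summer hourly
#'   temperatures (see [summer_temperature_quantile()]).
#' @param delta_aic_rule Required AIC improvement (default 2).
#' @return An object of class `saturation_call` with `saturating`,
#'   `best_threshold`, `delta_aic_uncapped`, `delta_aic_grid_top`,
#'   `within_q95`, `temp_q95` and `rule`.
#' @export
classify_saturation <- function(profile, temp_q95, delta_aic_rule = 2) {
  stopifnot(inherits(profile, "threshold_profile"))
  if (mean(!is.na(profile$aic)) < 0.8)
    stop("profile incomplete over more than 20% of the grid", call. = FALSE)
  best_aic <- min(profile$aic, na.rm = TRUE)
  margin_unc <- profile$aic_uncapped - best_aic
  top_aic <- profile$aic[length(profile$aic)]
  margin_top <- if (is.na(top_aic)) NA_real_ else top_aic - best_aic
  within <- profile$best_threshold <= temp_q95
  structure(list(saturating = isTRUE(margin_unc >= delta_aic_rule && within),
                 best_threshold = profile$best_threshold,
                 delta_aic_uncapped = margin_unc,
                 delta_aic_grid_top = margin_top,
                 within_q95 = within, temp_q95 = temp_q95,
                 rule = delta_aic_rule), class = "saturation_call")
}

#' @export
print.saturation_call <- function(x, ...) {
  cat(sprintf(
    "<saturation_call> %s: best cap %.2f degC (q95 %.2f), AIC margin vs uncapped %.3f (rule >= %.1f), vs grid top %.3f\n",
    if (x$saturating) "SATURATING" else "non-saturating",
    x$best_threshold, x$temp_q95, x$delta_aic_uncapped, x$rule,
    x$delta_aic_grid_top))
  invisible(x)
}

#' Estimate the temperature cap with leave-one-year-out uncertainty
#'
#' Runs the full-data AIC scan, then refits the whole scan once per omitted
#' year and reports the median, minimum and maximum of the per-refit best
#' caps. The estimate is flagged `meaningful` when the jackknife range lies
#' within the lower `q95` of observed snow-free summer temperatures, and
#' `saturating` per [classify_saturation()] on the full-data profile.
#'
#' @inheritParams scan_thresholds
#' @param temp_q95 Reference temperature quantile in deg C.
#' @param delta_aic_rule AIC-improvement rule for the saturation call.
#' @param species,location Labels carried into the result (taken from
#'   `flowers` when present).
#' @return An object of class `threshold_estimate`.
#' @export
jackknife_threshold <- function(flowers, temps, snow,
                                grid = default_threshold_grid(), k = 10,
                                temp_q95 = Inf, delta_aic_rule = 2,
                                species = NULL, location = NULL) {
  years <- sort(unique(flowers$year))
  if (length(years) < 3)
    stop("jackknife needs at least 3 years of data", call. = FALSE)
  designs <- threshold_designs(flowers, temps, snow, grid)
  full <- scan_thresholds(flowers, grid = grid, k = k, designs = designs)
  jk <- vapply(years, function(y)
    scan_thresholds(flowers, grid = grid, k = k, omit_year = y,
                    designs = designs)$best_threshold, 0)
  call <- classify_saturation(full, temp_q95, delta_aic_rule)
  structure(list(
    species = species %||% (if ("species" %in% names(flowers))
      flowers$species[1] else NA),
    location = location %||% (if ("location" %in% names(flowers))
      flowers$location[1] else NA),
    best_threshold = full$best_threshold,
    median_threshold = stats::median(jk),
    min_threshold = min(jk), max_threshold = max(jk),
    jackknife_thresholds = stats::setNames(jk, years),
    saturating = call$saturating,
    temp_q95 = temp_q95,
    meaningful = max(jk) <= temp_q95,
    profile = full, saturation_call = call), class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "<threshold_estimate> %s @ %s\n  cap %.2f degC (jackknife median %.2f, range [%.2f, %.2f], %d refits)\n  %s, %smeaningful (q95 = %.2f degC)\n",
    x$species, x$location, x$best_threshold, x$median_threshold,
    x$min_threshold, x$max_threshold, length(x$jackknife_thresholds),
    if (x$saturating) "saturating" else "non-saturating",
    if (x$meaningful) "" else "not ", x$temp_q95))
  invisible(x)
}
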