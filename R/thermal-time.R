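#' Accumulate thermal-time forcing from an hourly series
#'
#' Computes cumulative growing-degree-day forcing anchored at snowmelt. Each
#' hour contributes 0 degree-days while snow-covered (date before
#' `snowmelt_doy`) or when the temperature is at or below 0 deg C; otherwise
#' it contributes `min(T, tmax_threshold) / 24` degree-days (`T / 24` when no
#' cap is given). `forcing_type = "DOY"` yields calendar time (fractional
#' day-of-year) as the null forcing.
#'
#' @param series Gap-filled hourly series (any remaining `missing` hours are
#'   an error listing the offending timestamps).
#' @param snowmelt_doy Snowmelt day-of-year; must lie within the series span.
#'   Ignored for `"DOY"` forcing.
#' @param tmax_threshold Maximum temperature cap in deg C, or `NULL` for
#'   uncapped GDD.
#' @param forcing_type One of `"GDD"`, `"GDD_MAX"`, `"DOY"`; inferred from
#'   `tmax_threshold` when omitted.
#' @return An object of class `forcing_series`: a list with the series
#'   metadata (`location`, `treatment`, `year`, `forcing_type`,
#'   `tmax_threshold`, `snowmelt_doy`) and parallel vectors `time`
#'   (fractional day-of-year of each hour) and `cumulative` (degree-days at
#'   the end of that hour, or fractional DOY).
#' @export
accumulate_forcing <- function(series, snowmelt_doy = NULL,
                               tmax_threshold = NULL, forcing_type = NULL) {
  validate_hourly(series)
  if (!is.null(tmax_threshold) && is.na(tmax_threshold))
    tmax_threshold <- NULL
  type <- forcing_type %||% if (is.null(tmax_threshold)) "GDD" else "GDD_MAX"
  type <- match.arg(type, c("GDD", "GDD_MAX", "DOY"))
  if (type == "GDD_MAX" && is.null(tmax_threshold))
    stop("GDD_MAX forcing requires a tmax_threshold", call. = FALSE)
  if (type != "GDD_MAX" && !is.null(tmax_threshold))
    stop("tmax_threshold is only meaningful for GDD_MAX forcing",
         call. = FALSE)
  if (type == "DOY") {
    cumulative <- series$time
    snowmelt_doy <- snowmelt_doy %||% NA_real_
  } else {
    if (is.null(snowmelt_doy))
      stop("snowmelt_doy is required for GDD forcing", call. = FALSE)
    if (snowmelt_doy < min(series$doy) || snowmelt_doy > max(series$doy) + 1)
      stop("snowmelt_doy lies outside the series span", call. = FALSE)
    bad <- is.na(series$temp_c)
    if (any(bad))
      stop("series has unfilled missing hours at time(s): ",
           paste(utils::head(series$time[bad], 10), collapse = ", "),
           if (sum(bad) > 10) " ..." else "", call. = FALSE)
    t_eff <- if (is.null(tmax_threshold)) series$temp_c else
      pmin(series$temp_c, tmax_threshold)
    contrib <- ifelse(series$doy < snowmelt_doy | series$temp_c <= 0,
                      0, t_eff / 24)
    cumulative <- cumsum(contrib)
  }
  structure(list(
    location = if ("location" %in% names(series)) series$location[1] else NA,
    treatment = if ("treatment" %in% names(series)) series$treatment[1]
      else NA,
    year = if ("year" %in% names(series)) series$year[1] else NA,
    forcing_type = type,
    tmax_threshold = tmax_threshold,
    snowmelt_doy = as.numeric(snowmelt_doy),
    time = series$time,
    cumulative = as.numeric(cumulative)), class = "forcing_series")
}

#' @export
print.forcing_series <- function(x, ...) {
  cap <- if (is.null(x$tmax_threshold)) "none" else
    paste0(x$tmax_threshold, " degC")
  cat(sprintf(
    "<forcing_series> %s forcing (cap: %s), %s/%s year %s\n",
    x$forcing_type, cap, x$location, x$treatment, x$year))
  cat(sprintf("  span doy %.2f..%.2f, seasonal total %.3f\n",
              min(x$time), max(x$time), max(x$cumulative)))
  invisible(x)
}

#' Cumulative forcing at given timestamps
#'
#' Returns the cumulative forcing at the last completed hour at or before
#' each timestamp (an hour starting at `time` is completed at `time + 1/24`).
#' For `"DOY"` forcing the timestamp itself (fractional day-of-year) is
#' returned. Timestamps outside the covered span are a coverage error.
#'
#' @param forcing A `forcing_series` from [accumulate_forcing()].
#' @param t Numeric vector of fractional day-of-year timestamps.
#' @return Numeric vector of forcings (degree-days, or fractional DOY).
#' @export
forcing_at <- function(forcing, t) {
  stopifnot(inherits(forcing, "forcing_series"))
  if (forcing$forcing_type == "DOY") return(as.numeric(t))
  lo <- min(forcing$time)
  hi <- max(forcing$time) + 1 / 24
  # timestamps before the first record are definitionally zero while still
  # snow-covered; anything else outside the span is a coverage error
  if (any(t < lo - 1e-9 & t > forcing$snowmelt_doy) || any(t > hi + 1e-9))
    stop(sprintf("timestamp(s) outside the forcing span [%.3f, %.3f]",
                 lo, hi), call. = FALSE)
  idx <- findInterval(t - 1 / 24 + 1e-9, forcing$time)
  ifelse(idx == 0, 0, forcing$cumulative[pmax(idx, 1)])
}

#' Family of forcing series across a set of caps
#'
#' Computes one capped forcing series per threshold plus the uncapped series,
#' all sharing the input's timestamps. Forcing is pointwise non-decreasing in
#' the cap.
#'
#' @param series Gap-filled hourly series.
#' @param snowmelt_doy Snowmelt day-of-year.
#' @param thresholds Ascending numeric caps in deg C.
#' @return A named list of `forcing_series` (`tmax_<value>` ..., `uncapped`).
#' @export
forcing_family <- function(series, snowmelt_doy, thresholds) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be sorted strictly ascending", call. = FALSE)
  out <- lapply(thresholds, function(th)
    accumulate_forcing(series, snowmelt_doy, tmax_threshold = th))
  names(out) <- paste0("tmax_", thresholds)
  out$uncapped <- accumulate_forcing(series, snowmelt_doy)
  out
}
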