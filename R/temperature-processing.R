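#' Validate an hourly temperature series
#'
#' Checks the contract every downstream operation relies on: required
#' columns, strictly increasing timestamps on a complete 1-hour grid (missing
#' hours must be present as rows with `flag = "missing"` and `NA`
#' temperature), temperature/flag consistency, and a plausible temperature
#' range of [-60, 40] deg C.
#'
#' @param series Hourly series data frame (columns `doy`, `hour`, `time`,
#'   `temp_c`, `flag`; `year` optional for single-season series).
#' @return The series, invisibly; errors describe the violated invariant.
#' @export
validate_hourly <- function(series) {
  need <- c("doy", "hour", "time", "temp_c", "flag")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("hourly series is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(series) == 0) stop("hourly series is empty", call. = FALSE)
  d <- diff(series$time)
  if (any(abs(d - 1 / 24) > 1e-9))
    stop("timestamps must be strictly increasing with exactly 1-hour ",
         "spacing (insert missing hours as flag = \"missing\" rows)",
         call. = FALSE)
  na_temp <- is.na(series$temp_c)
  if (!all(na_temp == (series$flag == "missing")))
    stop("temp_c must be NA exactly where flag == \"missing\"",
         call. = FALSE)
  x <- series$temp_c[!na_temp]
  if (length(x) && (min(x) < -60 || max(x) > 40))
    stop("temperatures outside the plausible range [-60, 40] deg C",
         call. = FALSE)
  invisible(series)
}

#' Infill gaps in an hourly temperature series
#'
#' One-hour gaps (both adjacent hours present) are filled with the mean of
#' the previous and following hours (`flag = "infilled_1h"`). Runs of two or
#' more consecutive missing hours are filled hour-by-hour with the mean of
#' the values 24 h before and 24 h after (`flag = "infilled_24h"`); when only
#' one of the two reference hours exists, that single value is used and the
#' hour is flagged `"infilled_24h_single"`. Passes repeat until no further
#' hour can be filled, so the operation is idempotent; hours that remain
#' unfillable stay `"missing"` and are reported in the `"unfilled"`
#' attribute.
#'
#' @param series Hourly series (see [validate_hourly()]).
#' @return The series with formerly missing hours filled and re-flagged.
#'   Observed values and flags are never altered.
#' @export
infill_gaps <- function(series) {
  validate_hourly(series)
  vals <- series$temp_c
  flg <- as.character(series$flag)
  n <- length(vals)
  if (all(is.na(vals)))
    stop("series has no non-missing records to infill from", call. = FALSE)
  repeat {
    miss <- which(is.na(vals))
    if (!length(miss)) break
    runs <- split(miss, cumsum(c(1, diff(miss) != 1)))
    newvals <- vals; newflg <- flg; changed <- FALSE
    for (run in runs) {
      if (length(run) == 1) {
        i <- run
        if (i > 1 && i < n && !is.na(vals[i - 1]) && !is.na(vals[i + 1])) {
          newvals[i] <- (vals[i - 1] + vals[i + 1]) / 2
          newflg[i] <- "infilled_1h"
          changed <- TRUE
          next
        }
      }
      for (i in run) {
        refs <- c(if (i - 24 >= 1) vals[i - 24], if (i + 24 <= n) vals[i + 24])
        refs <- refs[!is.na(refs)]
        if (length(refs) == 2) {
          newvals[i] <- mean(refs); newflg[i] <- "infilled_24h"
          changed <- TRUE
        } else if (length(refs) == 1) {
          newvals[i] <- refs; newflg[i] <- "infilled_24h_single"
          changed <- TRUE
        }
      }
    }
    if (!changed) break
    vals <- newvals; flg <- newflg
  }
  out <- series
  out$temp_c <- vals
  out$flag <- flg
  left <- which(is.na(vals))
  if (length(left)) {
    warning(length(left), " hour(s) could not be infilled (reference hours ",
            "missing at both -24 h and +24 h)", call. = FALSE)
    attr(out, "unfilled") <- series$time[left]
  }
  out
}

#' Daily minimum, mean and maximum temperatures
#'
#' Summarizes an hourly series per calendar day over the hours that carry a
#' value, and counts observed vs infilled hours. Days with fewer than 20
#' available hours are flagged `low_coverage`.
#'
#' @param series Hourly series (infilled, or with gaps tolerated).
#' @return Data frame with columns `year` (if present in the input), `doy`,
#'   `t_min`, `t_mean`, `t_max`, `n_hours_observed`, `n_hours_infilled`,
#'   `low_coverage`.
#' @export
daily_summaries <- function(series) {
  validate_hourly(series)
  has_year <- "year" %in% names(series)
  key <- if (has_year) paste(series$year, series$doy) else
    as.character(series$doy)
  idx <- split(seq_len(nrow(series)), factor(key, levels = unique(key)))
  rows <- lapply(idx, function(i) {
    x <- series$temp_c[i]
    ok <- !is.na(x)
    fl <- series$flag[i]
    data.frame(
      year = if (has_year) series$year[i][1] else NA_integer_,
      doy = series$doy[i][1],
      t_min = if (any(ok)) min(x[ok]) else NA_real_,
      t_mean = if (any(ok)) mean(x[ok]) else NA_real_,
      t_max = if (any(ok)) max(x[ok]) else NA_real_,
      n_hours_observed = sum(fl == "observed"),
      n_hours_infilled = sum(startsWith(fl, "infilled")),
      low_coverage = sum(ok) < 20)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!has_year) out$year <- NULL
  out
}

#' Daily warming-treatment effect with rolling means
#'
#' Per-day differences (warmed minus ambient) in daily minimum, mean and
#' maximum temperature on the dates common to both summaries, plus centered
#' rolling means whose window shrinks at the series edges.
#'
#' @param ambient,warmed Daily summaries from [daily_summaries()].
#' @param window Rolling-mean window in days.
#' @return Data frame with columns `doy` (and `year` if present), `d_min`,
#'   `d_mean`, `d_max`, `roll_min`, `roll_mean`, `roll_max`.
#' @export
warming_effect <- function(ambient, warmed, window = 7) {
  by <- intersect(c("year", "doy"), intersect(names(ambient), names(warmed)))
  m <- merge(ambient, warmed, by = by, suffixes = c("_amb", "_wrm"))
  if (nrow(m) == 0)
    stop("ambient and warmed summaries share no dates", call. = FALSE)
  m <- m[do.call(order, m[by]), ]
  out <- m[by]
  out$d_min <- m$t_min_wrm - m$t_min_amb
  out$d_mean <- m$t_mean_wrm - m$t_mean_amb
  out$d_max <- m$t_max_wrm - m$t_max_amb
  roll_by <- if ("year" %in% by) factor(out$year) else
    factor(rep(1, nrow(out)))
  roll1 <- function(x) as.numeric(unsplit(
    lapply(split(x, roll_by), rolling_mean, window = window), roll_by))
  out$roll_min <- roll1(out$d_min)
  out$roll_mean <- roll1(out$d_mean)
  out$roll_max <- roll1(out$d_max)
  rownames(out) <- NULL
  out
}

#' Empirical quantile of snow-free summer hourly temperatures
#'
#' Restricts an hourly series to the snow-free part of a configurable summer
#' window and returns the type-7 (linear-interpolation) empirical quantile.
#' Used to judge whether an estimated temperature cap lies within the range
#' of commonly observed temperatures.
#'
#' @param series Hourly series, typically ambient treatment; multiple years
#'   are pooled as supplied.
#' @param q Probability in (0, 1); default 0.95.
#' @param snowmelt_doy Scalar snowmelt day-of-year, or a data frame with
#'   columns `year` and `melt_doy` when `series` spans several years.
#' @param summer_start,summer_end Day-of-year bounds of "summer"
#'   (June-August by default).
#' @return The quantile in deg C.
#' @export
summer_temperature_quantile <- function(series, q = 0.95, snowmelt_doy,
                                        summer_start = 152,
                                        summer_end = 243) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  if ("year" %in% names(series)) {
    invisible(lapply(split(series, series$year), validate_hourly))
  } else {
    validate_hourly(series)
  }
  if (is.data.frame(snowmelt_doy)) {
    if (!all(c("year", "melt_doy") %in% names(snowmelt_doy)))
      stop("snowmelt_doy data frame needs columns year and melt_doy",
           call. = FALSE)
    melt <- snowmelt_doy$melt_doy[match(series$year, snowmelt_doy$year)]
    if (anyNA(melt))
      stop("no snowmelt date for some years in the series", call. = FALSE)
  } else {
    melt <- rep(as.numeric(snowmelt_doy), nrow(series))
  }
  keep <- series$doy >= pmax(melt, summer_start) &
    series$doy <= summer_end & !is.na(series$temp_c)
  if (!any(keep))
    stop("no snow-free summer hours in the requested window", call. = FALSE)
  stats::quantile(series$temp_c[keep], probs = q, type = 7, names = FALSE)
}
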