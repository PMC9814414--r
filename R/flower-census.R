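group_cols <- function(df, cols) intersect(cols, names(df))

split_by <- function(df, cols) {
  if (!length(cols)) return(list(df))
  key <- do.call(paste, c(df[cols], sep = "\r"))
  split(df, factor(key, levels = unique(key)))
}

#' Derive per-plot new-flower counts from census observations
#'
#' New flowers opened since the previous census are estimated per plot and
#' census as the non-senesced count plus the increment in the senesced count:
#' `new_t = n_open_t + (n_senesced_t - n_senesced_{t-1})`, with the senesced
#' lag of the first census taken as 0. Negative values (observer error) are
#' clamped to zero with a warning; the pre-clamp value is kept in `new_raw`.
#'
#' @param obs Census observations with columns `plot`, `census_doy`,
#'   `n_open`, `n_senesced` (plus any of `species`, `location`, `treatment`,
#'   `year`, used as grouping keys). Dates must be strictly increasing within
#'   each plot.
#' @return `obs` with added columns `new_raw` and `new_flowers`.
#' @export
derive_new_flowers <- function(obs) {
  need <- c("plot", "census_doy", "n_open", "n_senesced")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("census table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(obs$n_open < 0) || any(obs$n_senesced < 0))
    stop("counts must be non-negative", call. = FALSE)
  keys <- group_cols(obs, c("species", "location", "treatment", "year",
                            "plot"))
  pieces <- split_by(obs, keys)
  n_clamped <- 0L
  pieces <- lapply(pieces, function(g) {
    if (is.unsorted(g$census_doy, strictly = TRUE))
      stop("census dates must be strictly increasing within each plot",
           call. = FALSE)
    prev <- c(0, g$n_senesced[-nrow(g)])
    g$new_raw <- g$n_open + g$n_senesced - prev
    g$new_flowers <- pmax(0, g$new_raw)
    n_clamped <<- n_clamped + sum(g$new_raw < 0)
    g
  })
  if (n_clamped > 0)
    warning(n_clamped, " negative new-flower value(s) clamped to 0",
            call. = FALSE)
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  out
}

#' Sum per-plot new-flower series over plots
#'
#' Aggregates plot-level counts to a single series per species x location x
#' treatment x year. All plots within a group must share the same census
#' schedule.
#'
#' @param per_plot Output of [derive_new_flowers()].
#' @return Data frame with one row per group x census, the count columns
#'   summed over plots, and `n_plots`.
#' @export
aggregate_plots <- function(per_plot) {
  keys <- group_cols(per_plot, c("species", "location", "treatment", "year"))
  pieces <- split_by(per_plot, keys)
  rows <- lapply(pieces, function(g) {
    scheds <- split(g$census_doy, g$plot)
    if (length(unique(vapply(scheds, paste, "", collapse = ","))) > 1)
      stop("census schedules differ across plots within a group",
           call. = FALSE)
    sums <- c("n_open", "n_senesced", "new_raw", "new_flowers")
    sums <- intersect(sums, names(g))
    agg <- stats::aggregate(g[sums], by = list(census_doy = g$census_doy),
                            FUN = sum)
    agg <- agg[order(agg$census_doy), c("census_doy", sums)]
    meta <- g[rep(1, nrow(agg)), keys, drop = FALSE]
    out <- cbind(meta, agg)
    out$n_plots <- length(scheds)
    out
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Anchor a series whose first census already has flowers
#'
#' When the first census of a season contains more than zero flowers, the
#' last flower-free date is estimated as two days before the earliest
#' first-flowering date from the early-season survey, and a zero-count census
#' is prepended there. Applies to a single species x location x treatment x
#' year series.
#'
#' @param series Aggregated series (one group) from [aggregate_plots()].
#' @param first_flower_doy First-flowering date(s) (day-of-year) from the
#'   early-season survey; the minimum is used.
#' @return The series, with a zero census prepended and an `anchored` column
#'   set when the rule fires; unchanged otherwise.
#' @export
anchor_first_census <- function(series, first_flower_doy = NULL) {
  series <- series[order(series$census_doy), , drop = FALSE]
  if (!"anchored" %in% names(series)) series$anchored <- FALSE
  if (series$new_flowers[1] == 0) return(series)
  if (is.null(first_flower_doy) || all(is.na(first_flower_doy)))
    stop("first census has flowers but no first-flowering date is available",
         call. = FALSE)
  ins <- min(first_flower_doy, na.rm = TRUE) - 2
  if (ins >= series$census_doy[1])
    stop("anchor date (first flowering - 2 days) is not earlier than the ",
         "first census", call. = FALSE)
  zero <- series[1, , drop = FALSE]
  zero$census_doy <- ins
  for (col in intersect(c("n_open", "n_senesced", "new_raw", "new_flowers"),
                        names(zero)))
    zero[[col]] <- 0
  zero$anchored <- TRUE
  out <- rbind(zero, series)
  rownames(out) <- NULL
  out
}

#' Assign intercensus intervals and midpoint dates
#'
#' The interval of census `t` is `date_t - date_{t-1}`; the first census,
#' which has no predecessor, is assigned a typical interval
#' (`default_first_interval`, 7 days). The flowering date of each census is
#' its interval midpoint, `date_t - interval_t / 2`, kept at fractional-day
#' resolution.
#'
#' @param series Aggregated series (one group), censuses ordered by date.
#' @param default_first_interval Interval assigned to the first census.
#' @return The series with added columns `interval` and `midpoint`.
#' @export
assign_midpoints <- function(series, default_first_interval = 7) {
  d <- series$census_doy
  if (anyDuplicated(d))
    stop("duplicate census dates", call. = FALSE)
  if (is.unsorted(d, strictly = TRUE))
    stop("censuses must be ordered by date", call. = FALSE)
  series$interval <- c(default_first_interval, diff(d))
  series$midpoint <- d - series$interval / 2
  series
}

#' Screen species x location combinations for inclusion
#'
#' A season "has a determinable flowering peak" when the maximum count falls
#' at neither the first nor the last census and the seasonal total reaches
#' `min_total`. A species x location combination is included when at least
#' `min_years` ambient seasons qualify.
#'
#' @param flowers Aggregated new-flower series for all groups (columns
#'   `species`, `location`, `treatment`, `year`, `census_doy`,
#'   `new_flowers`).
#' @param min_years Minimum qualifying ambient years (default 10).
#' @param total_years Total survey years, recorded for context (default 13).
#' @param min_total Minimum seasonal flower total for a determinable peak.
#' @return A list with `included` (species, location, n_qualifying_years,
#'   included flag) and `log` (one row per species x location x treatment x
#'   year with the qualification decision and reason).
#' @export
screen_inclusion <- function(flowers, min_years = 10, total_years = 13,
                             min_total = 5) {
  keys <- c("species", "location", "treatment", "year")
  miss <- setdiff(c(keys, "census_doy", "new_flowers"), names(flowers))
  if (length(miss))
    stop("flowers table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  pieces <- split_by(flowers, keys)
  log <- do.call(rbind, lapply(pieces, function(g) {
    g <- g[order(g$census_doy), ]
    tot <- sum(g$new_flowers)
    pk <- which.max(g$new_flowers)
    interior <- nrow(g) >= 3 && pk != 1 && pk != nrow(g)
    reason <- if (tot < min_total) "seasonal total below minimum"
      else if (!interior) "peak at a boundary census"
      else "ok"
    cbind(g[1, keys, drop = FALSE],
          data.frame(seasonal_total = tot,
                     determinable_peak = tot >= min_total && interior,
                     reason = reason))
  }))
  rownames(log) <- NULL
  amb <- log[log$treatment == "ambient" & log$determinable_peak, ]
  combos <- unique(log[c("species", "location")])
  combos$n_qualifying_years <- mapply(function(s, l)
    sum(amb$species == s & amb$location == l), combos$species,
    combos$location)
  combos$included <- combos$n_qualifying_years >= min_years
  rownames(combos) <- NULL
  list(included = combos, log = log,
       criteria = list(min_years = min_years, total_years = total_years,
                       min_total = min_total))
}

#' Census tables to seasonal new-flower series
#'
#' Convenience wrapper running the census module end-to-end for every
#' species x location x treatment x year group: per-plot derivation
#' ([derive_new_flowers()]), plot aggregation ([aggregate_plots()]),
#' first-census anchoring where needed ([anchor_first_census()]), and
#' interval/midpoint assignment ([assign_midpoints()]).
#'
#' @param censuses Plot-level census table.
#' @param first_flower Optional first-flowering table (columns `species`,
#'   `location`, `treatment`, `year`, `first_flower_doy`) consulted when a
#'   group's first census already has flowers.
#' @param default_first_interval Interval assigned to each first census.
#' @return One data frame of new-flower series across groups, with
#'   `interval`, `midpoint` and `anchored` columns.
#' @export
census_to_flowers <- function(censuses, first_flower = NULL,
                              default_first_interval = 7) {
  agg <- aggregate_plots(derive_new_flowers(censuses))
  keys <- group_cols(agg, c("species", "location", "treatment", "year"))
  pieces <- split_by(agg, keys)
  pieces <- lapply(pieces, function(g) {
    ff <- NULL
    if (!is.null(first_flower) && g$new_flowers[1] > 0) {
      sel <- rep(TRUE, nrow(first_flower))
      for (k in intersect(keys, names(first_flower)))
        sel <- sel & first_flower[[k]] == g[[k]][1]
      if (any(sel)) ff <- first_flower$first_flower_doy[sel]
    }
    assign_midpoints(anchor_first_census(g, ff), default_first_interval)
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  out
}
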