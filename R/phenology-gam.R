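#' Build a model design table from flowers and forcing
#'
#' One row per census: the new-flower count, the forcing evaluated at the
#' census midpoint ([forcing_at()]), the log intercensus interval (the model
#' offset) and the year label (the random-effect grouping factor).
#'
#' @param flowers New-flower series with `midpoint`, `interval`,
#'   `new_flowers` and `year` columns (one species x location, typically
#'   ambient treatment, possibly spanning years).
#' @param forcings A single `forcing_series`, or a list of them named by
#'   year.
#' @return Data frame with columns `count`, `forcing`, `log_interval`,
#'   `year` (factor) and `midpoint`.
#' @export
build_design <- function(flowers, forcings) {
  need <- c("midpoint", "interval", "new_flowers", "year")
  miss <- setdiff(need, names(flowers))
  if (length(miss))
    stop("flowers table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(flowers$interval <= 0))
    stop("intercensus intervals must be positive", call. = FALSE)
  if (inherits(forcings, "forcing_series")) {
    yr <- if (is.na(forcings$year)) unique(flowers$year) else forcings$year
    forcings <- stats::setNames(list(forcings), as.character(yr[1]))
  }
  f <- numeric(nrow(flowers))
  for (y in unique(flowers$year)) {
    fr <- forcings[[as.character(y)]]
    if (is.null(fr))
      stop("no forcing series supplied for year ", y, call. = FALSE)
    i <- flowers$year == y
    f[i] <- tryCatch(forcing_at(fr, flowers$midpoint[i]),
                     error = function(e) stop(
                       "census midpoint outside forcing span in year ", y,
                       ": ", conditionMessage(e), call. = FALSE))
  }
  data.frame(count = flowers$new_flowers, forcing = f,
             log_interval = log(flowers$interval),
             year = factor(flowers$year), midpoint = flowers$midpoint)
}

#' Fit the seasonal flower-count curve
#'
#' Penalized-spline Poisson regression of census counts on forcing: a
#' thin-plate smooth of the forcing covariate, a log intercensus-interval
#' offset, and year random intercepts (`s(year, bs = "re")`), fit by maximum
#' likelihood with `mgcv::gam`. With fewer than two years the random effect
#' degrades to the fixed intercept with a message. The basis dimension is
#' reduced (with a warning) when the data carry fewer distinct forcing values
#' than requested.
#'
#' @param design Design table from [build_design()].
#' @param k Spline basis dimension (default 10).
#' @return An object of class `phenology_fit` wrapping the `gam` fit, with
#'   elements `aic`, `loglik`, `edf`, `k`, `has_ranef`, `converged`,
#'   `train_range` and `n`.
#' @export
fit_phenology_gam <- function(design, k = 10) {
  stopifnot(all(c("count", "forcing", "log_interval", "year") %in%
                  names(design)))
  if (k < 4) stop("basis dimension k must be >= 4", call. = FALSE)
  if (sum(design$count) == 0)
    stop("all counts are zero: the seasonal curve is degenerate",
         call. = FALSE)
  if (any(!is.finite(design$forcing)))
    stop("non-finite forcing values in the design", call. = FALSE)
  design$year <- droplevels(factor(design$year))
  nuniq <- length(unique(design$forcing))
  if (nuniq < 5)
    stop("too few distinct forcing values to fit a smooth", call. = FALSE)
  k_use <- min(k, nuniq - 1)
  if (k_use < k)
    warning("basis dimension reduced to ", k_use,
            " (only ", nuniq, " distinct forcing values)", call. = FALSE)
  has_ranef <- nlevels(design$year) >= 2
  form <- if (has_ranef)
    count ~ s(forcing, k = k_use) + s(year, bs = "re") + offset(log_interval)
  else count ~ s(forcing, k = k_use) + offset(log_interval)
  fit <- mgcv::gam(form, family = stats::poisson(), data = design,
                   method = "ML")
  if (!has_ranef)
    message("fewer than 2 years: year random effect dropped ",
            "(fixed intercept only)")
  if (!fit$converged)
    warning("phenology GAM did not converge", call. = FALSE)
  structure(list(gam = fit, k = k_use, has_ranef = has_ranef,
                 aic = stats::AIC(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 edf = sum(fit$edf),
                 converged = fit$converged,
                 train_range = range(design$forcing),
                 n = nrow(design)),
            class = "phenology_fit")
}

#' @export
print.phenology_fit <- function(x, ...) {
  cat(sprintf(
    "<phenology_fit> Poisson GAM, k = %d%s, n = %d\n  AIC %.3f, logLik %.3f, edf %.2f%s\n",
    x$k, if (x$has_ranef) " + year random intercepts" else "", x$n,
    x$aic, x$loglik, x$edf,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Predict expected census counts from a fitted curve
#'
#' Expected count = `exp(spline(forcing) + log(interval) [+ year intercept])`.
#' Fixed-effects-only prediction (the default) is used for cross-treatment
#' and cross-year prediction. Forcing values beyond the fitted covariate
#' range are allowed but flagged in the `"extrapolated"` attribute.
#'
#' @param fit A `phenology_fit`.
#' @param forcing Forcing values at the prediction midpoints.
#' @param interval Intercensus intervals in days (> 0).
#' @param use_random_effects Include the year intercept (requires `year`).
#' @param year Year label for random-effect prediction.
#' @return Numeric vector of expected counts.
#' @export
predict_counts <- function(fit, forcing, interval,
                           use_random_effects = FALSE, year = NULL) {
  stopifnot(inherits(fit, "phenology_fit"))
  if (length(interval) == 1) interval <- rep(interval, length(forcing))
  if (any(interval <= 0))
    stop("intercensus intervals must be > 0", call. = FALSE)
  nd <- data.frame(forcing = forcing, log_interval = log(interval))
  if (fit$has_ranef) {
    lev <- levels(fit$gam$model$year)
    y <- as.character(year %||% lev[1])
    if (use_random_effects && !all(y %in% lev))
      stop("year not among the fitted levels", call. = FALSE)
    nd$year <- factor(if (all(y %in% lev)) y else lev[1], levels = lev)
  }
  excl <- if (fit$has_ranef && !use_random_effects) "s(year)" else NULL
  mu <- as.numeric(mgcv::predict.gam(fit$gam, newdata = nd,
                                     type = "response", exclude = excl))
  attr(mu, "extrapolated") <- forcing < fit$train_range[1] |
    forcing > fit$train_range[2]
  mu
}
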