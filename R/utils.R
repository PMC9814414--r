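`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and a label
#'
#' Stage- and replicate-level seeds are spawned deterministically from one
#' master seed so that every stochastic stage of a run is reproducible from a
#' single integer. The result is always a positive value below 2^31.
#'
#' @param seed Master seed (integer).
#' @param label Character label naming the stage/replicate.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629) + 1L
}

# meanlog/sdlog of a lognormal with given arithmetic mean and coefficient of
# variation
lognormal_params <- function(mean, cv) {
  stopifnot(mean > 0, cv > 0)
  sdlog <- sqrt(log1p(cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# centered rolling mean with a shrinking window at the series edges
rolling_mean <- function(x, window) {
  as.numeric(zoo::rollapply(x, width = window, FUN = mean,
                            partial = TRUE, align = "center"))
}

# day-of-year (integer) + year -> ISO-8601 timestamp string at hour resolution
iso_timestamp <- function(year, doy, hour) {
  d <- as.Date(doy - 1, origin = as.Date(sprintf("%d-01-01", year)))
  sprintf("%sT%02d:00:00Z", format(d, "%Y-%m-%d"), hour)
}

rmse <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  sqrt(mean((a - b)^2))
}
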