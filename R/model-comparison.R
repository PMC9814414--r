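#' Normalize a seasonal count series to percentages
#'
#' Each census count is expressed as a percentage of the seasonal total, so
#' observed and predicted series are compared on the timing of flowering
#' rather than the absolute flower number. Values sum to 100; applying the
#' operation twice is the identity.
#'
#' @param counts Non-negative counts across a season's censuses.
#' @return Percentages summing to 100.
#' @export
normalize_seasonal <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- sum(counts)
  if (tot <= 0)
    stop("seasonal total is zero: percentages are undefined", call. = FALSE)
  counts / tot * 100
}

#' Evaluate a fitted model's predictive error on a target treatment
#'
#' Per year: predict expected counts at the target's census midpoints using
#' fixed effects only, with the forcing computed under the TARGET treatment's
#' temperatures and snowmelt; normalize both predicted and observed counts to
#' seasonal percentages; and report their RMSE in percentage points. Years
#' whose observed or predicted seasonal total is zero are excluded and
#' logged in the `"excluded"` attribute.
#'
#' @param fit `phenology_fit` trained on ambient data of the same species x
#'   location.
#' @param flowers_target Target new-flower series (with midpoints/intervals).
#' @param forcings_target Forcing series list named by year, computed under
#'   the target treatment with the same forcing type/cap the model was
#'   trained on.
#' @param model_type Label: `"DOY"`, `"GDD"` or `"GDD_MAX"`.
#' @param treatment Target treatment label.
#' @return Data frame with columns `species`, `location`, `treatment`,
#'   `year`, `model_type`, `rmse`, `n_censuses`.
#' @export
evaluate_model <- function(fit, flowers_target, forcings_target, model_type,
                           treatment = NULL) {
  design <- build_design(flowers_target, forcings_target)
  years <- sort(unique(flowers_target$year))
  rows <- list(); excluded <- list()
  for (y in years) {
    i <- flowers_target$year == y
    obs <- flowers_target$new_flowers[i]
    pred <- predict_counts(fit, design$forcing[design$year == y],
                           flowers_target$interval[i])
    if (sum(obs) == 0 || sum(pred) == 0) {
      excluded[[as.character(y)]] <- if (sum(obs) == 0)
        "zero observed seasonal total" else "zero predicted seasonal total"
      next
    }
    rows[[as.character(y)]] <- data.frame(
      species = if ("species" %in% names(flowers_target))
        flowers_target$species[i][1] else NA,
      location = if ("location" %in% names(flowers_target))
        flowers_target$location[i][1] else NA,
      treatment = treatment %||% (if ("treatment" %in% names(flowers_target))
        flowers_target$treatment[i][1] else NA),
      year = y, model_type = model_type,
      rmse = rmse(normalize_seasonal(obs), normalize_seasonal(pred)),
      n_censuses = sum(i), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(species = character(), location = character(),
                      treatment = character(), year = integer(),
                      model_type = character(), rmse = numeric(),
                      n_censuses = integer())
  attr(out, "excluded") <- excluded
  out
}

forcing_list_for <- function(model_type, temps, snow, cap = NULL) {
  temps <- normalize_temps(temps)
  snow <- normalize_snow(snow)
  out <- lapply(names(temps), function(y) switch(
    model_type,
    DOY = accumulate_forcing(temps[[y]], forcing_type = "DOY"),
    GDD = accumulate_forcing(temps[[y]], snow[[y]]),
    GDD_MAX = accumulate_forcing(temps[[y]], snow[[y]],
                                 tmax_threshold = cap)))
  stats::setNames(out, names(temps))
}

#' Compare DOY, GDD and capped-GDD models across treatments
#'
#' Fits the three seasonal models on ambient data (the cap of the GDD_MAX
#' model is the full-data ambient estimate supplied by the caller), then
#' evaluates each on every target treatment with forcings computed under that
#' treatment's own temperatures and snowmelt dates.
#'
#' @param flowers_train Ambient new-flower series used for fitting.
#' @param targets Named list of targets; each element is a list with
#'   `flowers`, `temps`, `snow` (the name is the treatment label).
#' @param temps_train,snow_train Ambient temperatures/snowmelt for fitting.
#' @param tmax_threshold Estimated cap (deg C) for the GDD_MAX model.
#' @param k Spline basis dimension.
#' @return Data frame of per species x location x treatment x year x model
#'   RMSE rows (see [evaluate_model()]).
#' @export
compare_forcing_models <- function(flowers_train, temps_train, snow_train,
                                   targets, tmax_threshold, k = 10) {
  models <- c("DOY", "GDD", "GDD_MAX")
  rows <- list()
  for (m in models) {
    ftrain <- forcing_list_for(m, temps_train, snow_train, tmax_threshold)
    fit <- suppressWarnings(
      fit_phenology_gam(build_design(flowers_train, ftrain), k = k))
    for (tr in names(targets)) {
      tg <- targets[[tr]]
      ftr <- forcing_list_for(m, tg$temps, tg$snow, tmax_threshold)
      rows[[paste(m, tr)]] <- evaluate_model(fit, tg$flowers, ftr, m,
                                             treatment = tr)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Summarize RMSE distributions per model and treatment
#'
#' Median and quartiles of the per species x location x year RMSE values in
#' each model_type x treatment cell, the unit over which the predictive
#' comparison is averaged.
#'
#' @param results Rows from [evaluate_model()] / [compare_forcing_models()].
#' @return Data frame with columns `model_type`, `treatment`, `n`, `q25`,
#'   `median`, `q75`.
#' @export
summarize_rmse <- function(results) {
  stopifnot(all(c("model_type", "treatment", "rmse") %in% names(results)))
  pieces <- split(results,
                  list(results$model_type, results$treatment), drop = TRUE)
  out <- do.call(rbind, lapply(pieces, function(g) data.frame(
    model_type = g$model_type[1], treatment = g$treatment[1],
    n = nrow(g),
    q25 = stats::quantile(g$rmse, 0.25, names = FALSE),
    median = stats::median(g$rmse),
    q75 = stats::quantile(g$rmse, 0.75, names = FALSE),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$treatment, out$model_type), ]
}
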