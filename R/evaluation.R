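# External-validation statistics: relative prediction error and its
# summaries (median PE, MPE, relative RMSE), the bias/precision acceptance
# rules, Bland-Altman summaries, and the model-by-model evaluation loop.

#' Relative prediction errors (percent)
#'
#' `PE_i = (C_i,pred - C_obs) / C_obs x 100` for each retained
#' observation; `which` selects population (`"pred"`) or individual
#' (`"ipred"`) predictions.
#'
#' @param series Prediction series from [prediction_series()].
#' @param which `"pred"` or `"ipred"`.
#' @return Numeric vector of PE in percent.
#' @export
prediction_errors <- function(series, which = c("pred", "ipred")) {
  which <- match.arg(which)
  if (any(series$obs <= 0)) {
    stop("prediction_errors(): non-positive observed concentration; ",
         "BLQ records must be excluded upstream", call. = FALSE)
  }
  (series[[which]] - series$obs) / series$obs * 100
}

#' Summary statistics of a prediction-error vector
#'
#' @param pe Numeric vector of PE in percent (non-empty).
#' @return `data.frame` with `n`, `median_pe`, `mpe` (mean PE) and `rmse`
#'   (root mean squared PE), all in percent.
#' @export
summarize_errors <- function(pe) {
  if (!length(pe)) stop("summarize_errors(): empty PE vector", call. = FALSE)
  data.frame(n = length(pe),
             median_pe = stats::median(pe),
             mpe = mean(pe),
             rmse = sqrt(mean(pe^2)))
}

#' Bias and precision acceptance flags
#'
#' A model is acceptably unbiased when both the median and the mean PE are
#' strictly within +-20%, and acceptably precise when RMSE <= 30%
#' (inclusive).
#'
#' @param summary One row from [summarize_errors()].
#' @return `data.frame` with logical `acceptable_bias` and
#'   `acceptable_precision`.
#' @export
acceptance_flags <- function(summary) {
  data.frame(
    acceptable_bias = abs(summary$median_pe) < 20 & abs(summary$mpe) < 20,
    acceptable_precision = summary$rmse <= 30
  )
}

#' Bland-Altman summary of the prediction errors
#'
#' Differences are the PE in percent; the reference axis is the mean of
#' observed and predicted concentration (conventional) or the observation
#' alone.  Limits of agreement are mean +- 1.96 x SD of the PE.
#'
#' @inheritParams prediction_errors
#' @param reference `"mean"` (of observation and prediction) or `"obs"`.
#' @return List with `mean_pe`, `lower_limit`, `upper_limit` (percent) and
#'   `points` (`data.frame` of `x` = reference concentration, `y` = PE).
#' @export
bland_altman <- function(series, which = c("pred", "ipred"),
                         reference = c("mean", "obs")) {
  which <- match.arg(which)
  reference <- match.arg(reference)
  if (nrow(series) < 2) {
    stop("bland_altman(): at least two points required", call. = FALSE)
  }
  pe <- prediction_errors(series, which)
  x <- if (reference == "mean") (series$obs + series[[which]]) / 2 else
    series$obs
  m <- mean(pe)
  s <- stats::sd(pe)
  list(mean_pe = m, lower_limit = m - 1.96 * s, upper_limit = m + 1.96 * s,
       points = data.frame(x = x, y = pe))
}

#' Evaluate a catalog of models against a dataset
#'
#' Runs the full external-validation pipeline for every model: MAP
#' estimation per patient, population (PRED) and individual (IPRED)
#' predictions at the recorded sampling times, prediction errors and their
#' summaries, and the acceptance flags.  Patients whose MAP fit fails are
#' excluded from the IPRED summary but retained in PRED; the exclusion
#' count is reported, never silently dropped.
#'
#' @param catalog Named list of `mtx_model` objects.
#' @param dataset List of `mtx_individual` objects.
#' @param config [map_config()] used for every fit (deterministic given
#'   its seed).
#' @return List with `summary` (one row per model x prediction type:
#'   `model`, `type`, `n`, `median_pe`, `mpe`, `rmse`, the acceptance
#'   flags and `n_failed_fits`), `series` (per-model prediction series),
#'   and `estimates` (per-model list of eta estimates).
#' @export
evaluate_models <- function(catalog, dataset, config = map_config()) {
  stopifnot(length(dataset) > 0)
  rows <- list()
  all_series <- list()
  all_estimates <- list()
  for (m in catalog) {
    series_list <- list()
    est_list <- list()
    failed <- 0L
    for (d in dataset) {
      est <- tryCatch(estimate_etas(m, d, config), error = function(e) NULL)
      if (is.null(est)) failed <- failed + 1L
      ser <- prediction_series(m, d, est)
      ser$fit_ok <- !is.null(est)
      series_list[[d$covariates$patient_id]] <- ser
      est_list[[d$covariates$patient_id]] <- est
    }
    series <- do.call(rbind, series_list)
    rownames(series) <- NULL
    for (type in c("PRED", "IPRED")) {
      ser_t <- if (type == "IPRED") series[series$fit_ok, , drop = FALSE] else
        series
      pe <- prediction_errors(ser_t, tolower(type))
      smry <- summarize_errors(pe)
      stopifnot(smry$rmse >= abs(smry$mpe) - 1e-9)  # Jensen
      rows[[paste(m$name, type)]] <- cbind(
        data.frame(model = m$name, type = type),
        smry, acceptance_flags(smry),
        data.frame(n_failed_fits = failed))
    }
    all_series[[m$name]] <- series
    all_estimates[[m$name]] <- est_list
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, series = all_series, estimates = all_estimates)
}
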