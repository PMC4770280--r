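# Model evaluation against observed data: unit normalization, bias (MPE)
# and precision (MAPE) with t-based 95% confidence intervals, R^2.

#' Normalize a cell amount to cells per kg of organ
#'
#' @param amount Cell amount (cells).
#' @param organ_mass Organ mass in kg (organ volume at density 1 kg/L).
#' @return Concentration in cells/kg.
#' @export
normalize_to_cells_per_kg <- function(amount, organ_mass) {
  if (any(!is.finite(organ_mass)) || any(organ_mass <= 0)) {
    stop("organ mass must be positive", call. = FALSE)
  }
  amount / organ_mass
}

#' Prediction error statistics (bias and precision)
#'
#' Percentage prediction errors relative to the observations:
#' `MPE = (100/N) * sum((pred - obs)/obs)` (bias) and
#' `MAPE = (100/N) * sum(|pred - obs|/obs)` (precision), each with a
#' t-based confidence interval over the per-pair relative errors
#' (`mean +/- t_{1-alpha/2, N-1} * SE`). Also reports the log-scale
#' R-squared of predicted vs observed when there are at least 3 pairs.
#'
#' @param predicted,observed Paired series, `observed > 0`, length >= 2.
#' @param conf_level Confidence level (default 0.95).
#' @return A `prediction_comparison`: `n`, `mpe`, `mpe_ci`, `mape`,
#'   `mape_ci` (all in %), `r2`, and the per-pair `errors_pct`.
#' @export
prediction_errors <- function(predicted, observed, conf_level = 0.95) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  n <- length(observed)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  if (any(observed <= 0)) stop("observed values must be positive", call. = FALSE)
  e <- 100 * (predicted - observed) / observed
  ae <- abs(e)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  ci <- function(x) {
    se <- stats::sd(x) / sqrt(n)
    mean(x) + c(-1, 1) * tcrit * se
  }
  r2 <- if (n >= 3 && all(predicted >= 0))
    tryCatch(goodness_of_fit(predicted, observed), error = function(e) NA_real_)
  else NA_real_
  structure(list(n = n, mpe = mean(e), mpe_ci = ci(e),
                 mape = mean(ae), mape_ci = ci(ae),
                 r2 = r2, errors_pct = e, conf_level = conf_level),
            class = "prediction_comparison")
}

#' @export
print.prediction_comparison <- function(x, ...) {
  cl <- 100 * x$conf_level
  cat(sprintf("<prediction_comparison> N = %d\n", x$n))
  cat(sprintf("  MPE  %+.2f%% (%g%% CI %.2f to %.2f)\n",
              x$mpe, cl, x$mpe_ci[1], x$mpe_ci[2]))
  cat(sprintf("  MAPE %.2f%% (%g%% CI %.2f to %.2f)\n",
              x$mape, cl, x$mape_ci[1], x$mape_ci[2]))
  if (is.finite(x$r2)) cat(sprintf("  R^2 (log10) %.4f\n", x$r2))
  invisible(x)
}

#' Compare a simulation against an observed dataset
#'
#' Predicts at each dataset design point and computes MPE/MAPE/R^2.
#'
#' @param physiology,params,dose_events Model inputs (dose events default
#'   to the dataset's metadata).
#' @param data A `biodistribution_dataset` with positive concentrations.
#' @param ... Passed to [simulate_pbk()].
#' @return A `prediction_comparison`, with the paired table attached as
#'   attribute `"pairs"`.
#' @export
evaluate_predictions <- function(physiology, params, data,
                                 dose_events = NULL, ...) {
  if (is.null(dose_events)) dose_events <- attr(data, "dose_events")
  if (is.null(dose_events)) stop("dose_events required (none in metadata)",
                                 call. = FALSE)
  pred <- predict_dataset(physiology, params, dose_events, data, ...)
  cmp <- prediction_errors(pred, data$conc_cells_per_kg)
  attr(cmp, "pairs") <- data.frame(
    time_h = data$time_h, compartment = data$compartment,
    observed = data$conc_cells_per_kg, predicted = pred)
  cmp
}
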