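# Local sensitivity analysis: relative sensitivity coefficients (RSC).

rsc_concentration <- function(physiology, params, dose_events, output, t,
                              ...) {
  grid <- sort(unique(c(seq(0, max(t), length.out = 101), t)))
  sim <- simulate_pbk(physiology, params, dose_events, time_grid = grid, ...)
  concentration_per_kg(sim, output, t)
}

perturb_param <- function(params, parameter, factor) {
  v <- params_to_vector(params)
  if (!parameter %in% names(v)) {
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  }
  v[parameter] <- v[parameter] * factor
  vector_to_params(v)
}

#' Relative sensitivity coefficient of a model output
#'
#' Perturbs one cell-specific parameter by a small fraction (default +0.1%),
#' re-simulates, and returns the normalized response
#' `RSC = [(C' - C)/C] / (dP/P)`. Positive values mean the output moves
#' with the parameter, negative against it; RSC is dimensionless and
#' invariant to the parameter's units. `parameter = "dose"` perturbs the
#' administered amount instead (a known-linear control for which RSC = 1
#' exactly).
#'
#' @param physiology A `species_physiology`.
#' @param params A `cell_kinetic_params` (baseline).
#' @param dose_events Dose events.
#' @param parameter Parameter name in [params_to_vector()] notation, or
#'   `"dose"`.
#' @param output Output compartment (`"blood"` or one of [PBK_ORGANS]);
#'   the output quantity is the cells/kg concentration.
#' @param t Evaluation time in hours (default 24, when circulating cell
#'   numbers have reached a relatively steady state).
#' @param perturbation Fractional parameter change (default 0.001).
#' @param method `"forward"` (matching the +0.1% definition) or
#'   `"central"` (verification mode, two-sided).
#' @param ... Passed to [simulate_pbk()].
#' @return RSC (unitless scalar).
#' @export
relative_sensitivity <- function(physiology, params, dose_events, parameter,
                                 output, t = 24, perturbation = 0.001,
                                 method = c("forward", "central"), ...) {
  method <- match.arg(method)
  stopifnot(perturbation > 0)
  if (inherits(dose_events, "dose_event")) dose_events <- list(dose_events)
  base <- rsc_concentration(physiology, params, dose_events, output, t, ...)
  if (base <= 0) {
    stop("baseline concentration is zero at t = ", t,
         "; RSC is undefined", call. = FALSE)
  }
  sim_at <- function(factor) {
    if (identical(parameter, "dose")) {
      ev <- lapply(dose_events, function(e) {
        dose_event(e$route, e$amount * factor, e$time)
      })
      rsc_concentration(physiology, params, ev, output, t, ...)
    } else {
      rsc_concentration(physiology, perturb_param(params, parameter, factor),
                        dose_events, output, t, ...)
    }
  }
  if (method == "forward") {
    (sim_at(1 + perturbation) - base) / base / perturbation
  } else {
    (sim_at(1 + perturbation) - sim_at(1 - perturbation)) /
      (2 * perturbation * base)
  }
}

#' Sensitivity sweep over all cell-specific parameters
#'
#' Computes the RSC of each of the 25 cell-specific parameters for one or
#' more output compartments at one or more times (one simulation per
#' parameter; outputs share the perturbed trajectory).
#'
#' @param physiology A `species_physiology`.
#' @param params Baseline `cell_kinetic_params`.
#' @param dose_events Dose events.
#' @param outputs Output compartments (default liver and heart, the organs
#'   most relevant to the clinical indications).
#' @param t Evaluation time(s) in hours (default 24).
#' @param perturbation Fractional change (default 0.001).
#' @param ... Passed to [simulate_pbk()].
#' @return A `sensitivity_result` data frame with columns `parameter`,
#'   `output`, `time_h`, `rsc`, `perturbation`.
#' @export
sensitivity_sweep <- function(physiology, params, dose_events,
                              outputs = c("liver", "heart"), t = 24,
                              perturbation = 0.001, ...) {
  if (inherits(dose_events, "dose_event")) dose_events <- list(dose_events)
  grid <- sort(unique(c(seq(0, max(t), length.out = 101), t)))
  conc_all <- function(p) {
    sim <- simulate_pbk(physiology, p, dose_events, time_grid = grid, ...)
    outer_res <- sapply(outputs, function(o) concentration_per_kg(sim, o, t))
    matrix(outer_res, nrow = length(t),
           dimnames = list(NULL, outputs))
  }
  base <- conc_all(params)
  if (any(base <= 0)) {
    stop("baseline concentration is zero for some output; RSC undefined",
         call. = FALSE)
  }
  pnames <- names(params_to_vector(params))
  rows <- list()
  for (p in pnames) {
    pert <- conc_all(perturb_param(params, p, 1 + perturbation))
    rsc <- (pert - base) / base / perturbation
    for (o in outputs) {
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, output = o, time_h = t, rsc = rsc[, o],
        perturbation = perturbation, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' Highly sensitive parameters
#'
#' Filters a sensitivity sweep to entries with `|RSC|` above the threshold
#' (0.5 by convention), sorted by `|RSC|` descending.
#'
#' @param result A `sensitivity_result` from [sensitivity_sweep()].
#' @param threshold Absolute RSC threshold (default 0.5).
#' @return Subset of `result`, sorted, with a `flagged_highly_sensitive`
#'   column (always TRUE in the returned subset).
#' @export
classify_sensitive <- function(result, threshold = 0.5) {
  stopifnot(is.data.frame(result), nrow(result) > 0, "rsc" %in% names(result))
  hit <- result[abs(result$rsc) > threshold, , drop = FALSE]
  hit <- hit[order(-abs(hit$rsc)), , drop = FALSE]
  hit$flagged_highly_sensitive <- rep(TRUE, nrow(hit))
  rownames(hit) <- NULL
  hit
}
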