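# Parameter estimation from biodistribution time courses.

#' Construct / validate a biodistribution dataset
#'
#' Records of observed (or synthetic) cell concentrations per compartment
#' and time, as means over animals with standard deviations. `"blood"`
#' measurements are compared against the venous pool.
#'
#' @param records Data frame with columns `time_h`, `compartment`,
#'   `conc_cells_per_kg`, and optionally `sd`, `n`.
#' @param species Species label (metadata).
#' @param dose_events Dose events the data were collected under (metadata).
#' @return A `biodistribution_dataset` (data frame subclass with attributes).
#' @export
biodistribution_dataset <- function(records, species = NA_character_,
                                    dose_events = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("time_h", "compartment", "conc_cells_per_kg")
  if (!all(needed %in% names(records))) {
    stop("dataset must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!"sd" %in% names(records)) records$sd <- NA_real_
  if (!"n" %in% names(records)) records$n <- NA_integer_
  ok <- c("blood", PBK_ORGANS)
  bad <- setdiff(unique(records$compartment), ok)
  if (length(bad) > 0) {
    stop("unknown compartment(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(records$time_h < 0) || any(records$conc_cells_per_kg < 0)) {
    stop("times and concentrations must be non-negative", call. = FALSE)
  }
  structure(records, species = species, dose_events = dose_events,
            class = c("biodistribution_dataset", "data.frame"))
}

#' Read a biodistribution CSV
#'
#' CSV dialect: columns `time_h`, `compartment`, `conc_cells_per_kg`,
#' optional `sd`, `n`. Lines starting with `#` are comments.
#'
#' @param path CSV path.
#' @param species,dose_events Metadata passed to [biodistribution_dataset()].
#' @return A `biodistribution_dataset`.
#' @export
read_biodistribution_csv <- function(path, species = NA_character_,
                                     dose_events = NULL) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  biodistribution_dataset(tab, species = species, dose_events = dose_events)
}

#' Write a biodistribution dataset to CSV
#' @param data A `biodistribution_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biodistribution_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Model-predicted concentrations at the dataset's design points
#'
#' Simulates once over a grid covering the observation times and evaluates
#' the cells/kg concentration for each record.
#'
#' @param physiology A `species_physiology`.
#' @param params A `cell_kinetic_params`.
#' @param dose_events Dose events to simulate under.
#' @param data A `biodistribution_dataset`.
#' @param ... Passed to [simulate_pbk()].
#' @return Numeric vector of predictions aligned with `data` rows.
#' @export
predict_dataset <- function(physiology, params, dose_events, data, ...) {
  tmax <- max(data$time_h)
  grid <- sort(unique(c(seq(0, tmax, length.out = 201), data$time_h)))
  sim <- simulate_pbk(physiology, params, dose_events, time_grid = grid, ...)
  vapply(seq_len(nrow(data)), function(i) {
    concentration_per_kg(sim, data$compartment[i], data$time_h[i])
  }, 0)
}

default_param_bounds <- function() {
  v <- params_to_vector(load_kinetic_params("table1"))
  lower <- ifelse(grepl("partition", names(v)), 0.1, 1e-4)
  upper <- ifelse(grepl("partition", names(v)), 1e4, 1e2)
  names(lower) <- names(upper) <- names(v)
  list(lower = lower, upper = upper)
}

#' Fit cell-specific parameters to biodistribution data
#'
#' Bounded least squares on `log10(concentration + epsilon)`, the natural
#' scale for data spanning several orders of magnitude, using
#' Levenberg-Marquardt (`minpack.lm::nls.lm`) on log10-transformed
#' parameters. A fixed/free mask supports disease-specific re-estimation
#' where only one organ's parameter block is freed. Multi-start (perturbed
#' initial values, seeded) emulates manual escape from local minima; the
#' fit is deterministic given `init`, bounds, data and `seed`.
#'
#' @param data A `biodistribution_dataset`.
#' @param physiology A `species_physiology`.
#' @param init A `cell_kinetic_params` giving starting values (and the
#'   values at which fixed parameters are held).
#' @param dose_events Dose events the data were collected under; defaults
#'   to the dataset's metadata.
#' @param free Character vector of free parameter names in
#'   [params_to_vector()] notation (e.g. `c("lung.partition",
#'   "lung.k_arrest")`); default frees all 25.
#' @param lower,upper Named bound vectors on the natural scale; defaults
#'   bracket the fitted mouse values by at least an order of magnitude
#'   (partition in \[0.1, 1e4\], rates in \[1e-4, 1e2\] 1/h).
#' @param n_starts Number of optimizer starts (default 5; start 1 is
#'   `init`, the rest are seeded lognormal perturbations).
#' @param seed Seed for the perturbed starts.
#' @param epsilon Offset in cells/kg inside the log10 (default 1).
#' @param maxiter Maximum LM iterations per start.
#' @return A `fit_result`: `params` (full set, fixed merged), `free`,
#'   `objective` (sum of squared log10 residuals), `r2` overall and per
#'   compartment, `convergence` diagnostics.
#' @export
fit_parameters <- function(data, physiology, init, dose_events = NULL,
                           free = NULL, lower = NULL, upper = NULL,
                           n_starts = 5, seed = 1, epsilon = 1,
                           maxiter = 100) {
  stopifnot(inherits(data, "biodistribution_dataset"), nrow(data) > 0,
            inherits(init, "cell_kinetic_params"))
  if (is.null(dose_events)) dose_events <- attr(data, "dose_events")
  if (is.null(dose_events)) stop("dose_events required (none in metadata)",
                                 call. = FALSE)
  v0 <- params_to_vector(init)
  if (is.null(free)) free <- names(v0)
  bad <- setdiff(free, names(v0))
  if (length(bad) > 0) stop("unknown free parameter(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  b <- default_param_bounds()
  if (!is.null(lower)) b$lower[names(lower)] <- lower
  if (!is.null(upper)) b$upper[names(upper)] <- upper
  if (any(v0[free] < b$lower[free]) || any(v0[free] > b$upper[free])) {
    stop("init outside bounds for a free parameter", call. = FALSE)
  }
  obs_log <- log10(data$conc_cells_per_kg + epsilon)

  resid_fn <- function(theta_log) {
    v <- v0
    v[free] <- 10^theta_log
    pred <- predict_dataset(physiology, vector_to_params(v), dose_events, data)
    log10(pmax(pred, 0) + epsilon) - obs_log
  }

  # seeded multi-start on the log10 scale
  set.seed(seed)
  th0 <- log10(v0[free])
  lo <- log10(b$lower[free]); hi <- log10(b$upper[free])
  starts <- list(th0)
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1L)) {
      starts[[k + 1L]] <- pmin(hi, pmax(lo, th0 + stats::rnorm(length(th0), 0, 0.3)))
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- minpack.lm::nls.lm(par = st, lower = lo, upper = hi, fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = maxiter, ftol = 1e-10, ptol = 1e-10))
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  converged <- best$info %in% 1:4
  if (!converged) {
    warning("optimizer did not report convergence (info = ", best$info, ")")
  }
  v_hat <- v0
  v_hat[free] <- 10^best$par
  params_hat <- vector_to_params(v_hat)

  pred <- predict_dataset(physiology, params_hat, dose_events, data)
  r2_all <- tryCatch(goodness_of_fit(pred, data$conc_cells_per_kg,
                                     epsilon = epsilon),
                     error = function(e) NA_real_)
  r2_comp <- vapply(split(seq_len(nrow(data)), data$compartment), function(i) {
    tryCatch(goodness_of_fit(pred[i], data$conc_cells_per_kg[i],
                             epsilon = epsilon),
             error = function(e) NA_real_)
  }, 0)

  structure(list(
    params = params_hat, free = free, objective = best$deviance,
    r2 = r2_all, r2_by_compartment = r2_comp,
    predicted = pred,
    convergence = list(converged = converged, info = best$info,
                       message = best$message, iterations = best$niter,
                       n_starts = n_starts)
  ), class = "fit_result")
}

#' Goodness of fit (coefficient of determination)
#'
#' R-squared of the linear regression of predicted on observed
#' concentrations, computed by default on the log10 scale (the scale on
#' which biodistribution profiles are plotted and fitted).
#'
#' @param predicted,observed Paired concentration series (>= 3 points).
#' @param log10_scale Regress on `log10(x + epsilon)` (default TRUE).
#' @param epsilon Offset inside the log10.
#' @return R-squared (<= 1).
#' @export
goodness_of_fit <- function(predicted, observed, log10_scale = TRUE,
                            epsilon = 1) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  if (length(observed) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (log10_scale) {
    predicted <- log10(pmax(predicted, 0) + epsilon)
    observed <- log10(pmax(observed, 0) + epsilon)
  }
  if (stats::var(observed) == 0) {
    stop("observed series has zero variance", call. = FALSE)
  }
  fit <- stats::lm(predicted ~ observed)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((predicted - mean(predicted))^2)
  if (ss_tot == 0) return(0)            # constant predictions explain nothing
  1 - ss_res / ss_tot
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> objective %.6g, R^2 %.4f, %d free parameter(s)\n",
              x$objective, x$r2, length(x$free)))
  cat("  converged:", x$convergence$converged,
      "| LM info:", x$convergence$info, "\n")
  est <- params_to_vector(x$params)[x$free]
  print(signif(est, 5))
  invisible(x)
}
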