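# Synthetic biodistribution data with the statistical structure of the
# mouse flow-cytometry experiment (n animals per terminal time point,
# multiplicative measurement noise).

#' Default sampling schedule of the mouse experiment
#'
#' Terminal sampling at 5 min, 15 min, 1, 3, 10 and 20 hours post-injection.
#'
#' @return Numeric vector of times in hours.
#' @export
default_schedule <- function() c(5 / 60, 15 / 60, 1, 3, 10, 20)

#' Measured compartments of the mouse experiment
#' @return Character vector.
#' @export
default_compartments <- function() {
  c("blood", "lung", "liver", "spleen", "kidney", "heart")
}

#' Construct a measurement noise model
#'
#' Lognormal multiplicative noise: each animal's measurement is the true
#' concentration times a lognormal factor with unit mean and the stated
#' coefficient of variation; rare-event cytometry counts have right-skewed,
#' scale-proportional error. `cv = 0` is the degenerate noiseless limit.
#'
#' @param cv Coefficient of variation of the multiplicative factor
#'   (default 0.25).
#' @param n_animals Animals per (time, compartment) point (default 5).
#' @param seed RNG seed making the dataset reproducible.
#' @return A `noise_model`.
#' @export
noise_model <- function(cv = 0.25, n_animals = 5, seed = 1) {
  if (!is.finite(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (n_animals < 1) stop("n_animals must be >= 1", call. = FALSE)
  structure(list(cv = cv, n_animals = as.integer(n_animals),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate a synthetic biodistribution dataset
#'
#' Simulates the true cells/kg concentration for every (time, compartment)
#' design point, draws `n_animals` lognormal replicates with the noise
#' model's CV (unit-mean factors, so replicate means are unbiased for the
#' truth), and records their mean and standard deviation. With `cv = 0`
#' the recorded means equal the noiseless simulation exactly.
#'
#' @param physiology A `species_physiology`.
#' @param params Generating `cell_kinetic_params`.
#' @param dose_events Dose events (default: the mouse experiment's 5e5
#'   cells IV at t = 0).
#' @param schedule Sampling times in hours (default [default_schedule()]).
#' @param compartments Measured compartments (default
#'   [default_compartments()]).
#' @param noise A [noise_model()].
#' @return A `biodistribution_dataset` with the generating conditions in
#'   its metadata (attribute `"generator"`).
#' @export
generate_dataset <- function(physiology, params,
                             dose_events = dose_event("intravenous", 5e5),
                             schedule = default_schedule(),
                             compartments = default_compartments(),
                             noise = noise_model()) {
  stopifnot(inherits(noise, "noise_model"))
  if (inherits(dose_events, "dose_event")) dose_events <- list(dose_events)
  if (any(schedule <= min(vapply(dose_events, function(e) e$time, 0)))) {
    stop("sampling schedule must follow the first dose", call. = FALSE)
  }
  ok <- c("blood", PBK_ORGANS)
  if (length(compartments) == 0 || !all(compartments %in% ok)) {
    stop("invalid compartment list", call. = FALSE)
  }
  grid <- sort(unique(c(seq(0, max(schedule), length.out = 201), schedule)))
  sim <- simulate_pbk(physiology, params, dose_events, time_grid = grid)
  design <- expand.grid(time_h = schedule, compartment = compartments,
                        stringsAsFactors = FALSE)
  truth <- vapply(seq_len(nrow(design)), function(i) {
    concentration_per_kg(sim, design$compartment[i], design$time_h[i])
  }, 0)
  set.seed(noise$seed)
  if (noise$cv > 0) {
    sdlog <- sqrt(log(1 + noise$cv^2))
    meanlog <- -sdlog^2 / 2                     # unit-mean factor
    reps <- matrix(stats::rlnorm(nrow(design) * noise$n_animals,
                                 meanlog, sdlog),
                   nrow = nrow(design))
    vals <- truth * reps
    design$conc_cells_per_kg <- rowMeans(vals)
    design$sd <- apply(vals, 1, stats::sd)
  } else {
    design$conc_cells_per_kg <- truth
    design$sd <- 0
  }
  design$n <- noise$n_animals
  out <- biodistribution_dataset(design, species = physiology$species,
                                 dose_events = dose_events)
  attr(out, "generator") <- list(noise = noise, truth = truth,
                                 params = params)
  out
}
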