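# Administration routes as instantaneous state perturbations.

#' Construct a dose event
#'
#' A bolus administration of cells at a given time. Intravenous dosing
#' enters the central venous pool (tail-vein push is fast relative to the
#' first sampling time); intra-hepatic arterial dosing delivers the cells
#' directly into the hepatic vascular bed, bypassing the pulmonary
#' first-pass.
#'
#' @param route `"intravenous"` or `"intra_hepatic_arterial"`.
#' @param amount Number of cells (> 0; 0 is allowed for null simulations).
#' @param time Dose time in hours (default 0).
#' @return A `dose_event`.
#' @export
dose_event <- function(route = c("intravenous", "intra_hepatic_arterial"),
                       amount, time = 0) {
  route <- match.arg(route)
  if (!is.numeric(amount) || length(amount) != 1L || !is.finite(amount) ||
      amount < 0) {
    stop("dose amount must be a non-negative number", call. = FALSE)
  }
  if (!is.finite(time)) stop("dose time must be finite", call. = FALSE)
  structure(list(route = route, amount = as.numeric(amount),
                 time = as.numeric(time)),
            class = "dose_event")
}

#' Apply a dose event to a model state
#'
#' Adds the bolus to the route's target compartment as an instantaneous
#' concentration jump: IV adds `amount / venous_blood_volume` to the venous
#' pool; intra-hepatic arterial adds `amount / V_V_liver` to the liver
#' vascular concentration. Total cells increase by exactly `amount`.
#'
#' @param state Named state vector (see [state_names()]).
#' @param event A [dose_event()].
#' @param physiology A `species_physiology`.
#' @return The perturbed state vector.
#' @export
apply_dose <- function(state, event, physiology) {
  stopifnot(inherits(event, "dose_event"))
  if (event$route == "intravenous") {
    state[["C_venous"]] <- state[["C_venous"]] +
      event$amount / physiology$venous_blood_volume
  } else if (event$route == "intra_hepatic_arterial") {
    v_liver <- organ_row(physiology, "liver")$vascular_volume
    state[["C_liver"]] <- state[["C_liver"]] + event$amount / v_liver
  } else {
    stop("unsupported route '", event$route, "'", call. = FALSE)
  }
  state
}
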