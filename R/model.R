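# Eight-compartment PBK model of circulating MSCs: rate matrix, simulation,
# derived outputs.
#
# State vector (15 entries):
#   C_arterial, C_venous           central blood pool concentrations (cells/L)
#   C_<organ> x 6                  organ vascular concentrations (cells/L)
#   A_<organ> x 6                  arrested extravascular amounts (cells)
#   D_cum                          cumulative depleted cells (cells)
#
# Topology: venous blood -> lung (total cardiac output, in series) ->
# arterial blood -> {liver (hepatic artery), spleen, kidney, heart, rest}
# in parallel; spleen venous outflow drains into the liver (portal link),
# liver outflow = hepatic artery + splenic flow; all other organs drain to
# venous blood. Venous outflow of organ t leaves at concentration C_V_t/P_t.
# Arrest/release exchange the vascular pool with an arrested pool; depletion
# removes cells from arrested pools (organs) and from the central blood
# pools (blood depletion constant), all first order, into the sink D_cum.

state_names <- function() {
  c("C_arterial", "C_venous",
    paste0("C_", PBK_ORGANS),
    paste0("A_", PBK_ORGANS),
    "D_cum")
}

# Vector m such that total cells = sum(m * state); mass-conservation means
# m' A = 0 for the rate matrix A.
mass_weights <- function(physiology) {
  org <- physiology$organs[match(PBK_ORGANS, physiology$organs$name), ]
  w <- c(physiology$arterial_blood_volume, physiology$venous_blood_volume,
         org$vascular_volume, rep(1, length(PBK_ORGANS)), 1)
  names(w) <- state_names()
  w
}

#' Venous outflow concentration under a partition coefficient
#'
#' The partition coefficient `P` links the concentration in an organ's
#' vascular space to the concentration in the venous blood leaving it:
#' the outflow concentration is `C_V / P`. Large `P` means the organ's
#' microvascular environment retains cells relative to outgoing blood.
#'
#' @param c_vascular Concentration in the organ vascular space (cells/L).
#' @param partition Partition coefficient (unitless, > 0).
#' @return Outflow concentration in cells/L.
#' @examples
#' venous_outflow_concentration(100, 1)
#' @export
venous_outflow_concentration <- function(c_vascular, partition) {
  if (any(!is.finite(partition)) || any(partition <= 0)) {
    stop("partition coefficient must be positive", call. = FALSE)
  }
  c_vascular / partition
}

#' Build the linear rate matrix of the PBK system
#'
#' The model is linear in the state (first-order kinetics, flow-limited
#' transport), so the full dynamics are `d(state)/dt = A %*% state` with a
#' constant matrix `A`. The matrix is also the analytic Jacobian handed to
#' the stiff solver.
#'
#' @param physiology A `species_physiology`.
#' @param params A `cell_kinetic_params`.
#' @return A 15 x 15 matrix with dimnames equal to the state names.
#' @export
build_rate_matrix <- function(physiology, params) {
  validate_species_physiology(physiology)
  stopifnot(inherits(params, "cell_kinetic_params"))
  sn <- state_names()
  n <- length(sn)
  A <- matrix(0, n, n, dimnames = list(sn, sn))
  org <- physiology$organs[match(PBK_ORGANS, physiology$organs$name), ]
  kin <- params$organs                      # already in PBK_ORGANS order
  co <- physiology$cardiac_output
  v_art <- physiology$arterial_blood_volume
  v_ven <- physiology$venous_blood_volume
  kdb <- params$blood_k_depletion

  iC <- function(o) paste0("C_", o)
  iA <- function(o) paste0("A_", o)
  V <- stats::setNames(org$vascular_volume, org$name)
  Q <- stats::setNames(org$blood_flow, org$name)   # liver entry = hepatic artery
  P <- stats::setNames(kin$partition, kin$organ)
  ka <- stats::setNames(kin$k_arrest, kin$organ)
  kr <- stats::setNames(kin$k_release, kin$organ)
  kd <- stats::setNames(kin$k_depletion, kin$organ)
  q_liver_out <- Q[["liver"]] + Q[["spleen"]]      # hepatic artery + portal

  # arterial pool: fed by lung outflow, drains into systemic organs
  A["C_arterial", iC("lung")] <- co / P[["lung"]] / v_art
  A["C_arterial", "C_arterial"] <- -(co / v_art + kdb)

  # venous pool: collects liver/kidney/heart/rest outflows, feeds the lung
  for (o in c("liver", "kidney", "heart", "rest_of_body")) {
    q_out <- if (o == "liver") q_liver_out else Q[[o]]
    A["C_venous", iC(o)] <- A["C_venous", iC(o)] + q_out / P[[o]] / v_ven
  }
  A["C_venous", "C_venous"] <- -(co / v_ven + kdb)

  for (o in PBK_ORGANS) {
    q_out <- if (o == "liver") q_liver_out else Q[[o]]
    # inflow
    if (o == "lung") {
      A[iC(o), "C_venous"] <- co / V[[o]]
    } else if (o == "liver") {
      A[iC(o), "C_arterial"] <- Q[["liver"]] / V[[o]]
      A[iC(o), iC("spleen")] <- Q[["spleen"]] / P[["spleen"]] / V[[o]]
    } else {
      A[iC(o), "C_arterial"] <- Q[[o]] / V[[o]]
    }
    # outflow + arrest, release
    A[iC(o), iC(o)] <- A[iC(o), iC(o)] - q_out / P[[o]] / V[[o]] - ka[[o]]
    A[iC(o), iA(o)] <- kr[[o]] / V[[o]]
    # arrested pool
    A[iA(o), iC(o)] <- ka[[o]] * V[[o]]
    A[iA(o), iA(o)] <- -(kr[[o]] + kd[[o]])
    # depletion sink
    A["D_cum", iA(o)] <- kd[[o]]
  }
  A["D_cum", "C_arterial"] <- kdb * v_art
  A["D_cum", "C_venous"] <- kdb * v_ven
  A
}

#' Time derivative of the model state
#'
#' Evaluates the mass balances at a given state: flow-limited exchange
#' between compartments with partition-limited venous outflow, first-order
#' arrest/release between each organ's vascular and arrested pools,
#' first-order depletion from the arrested pools and the central blood
#' pools into the cumulative sink.
#'
#' @param state Named numeric state vector (see [state_names()] order:
#'   `C_arterial`, `C_venous`, `C_<organ>`, `A_<organ>`, `D_cum`).
#' @param params A `cell_kinetic_params`.
#' @param physiology A `species_physiology`.
#' @return Named numeric vector of derivatives, same order as `state`.
#' @export
state_derivative <- function(state, params, physiology) {
  A <- build_rate_matrix(physiology, params)
  sn <- state_names()
  if (!is.null(names(state))) {
    if (!all(sn %in% names(state))) stop("state is missing entries", call. = FALSE)
    state <- state[sn]
  } else if (length(state) != length(sn)) {
    stop("state must have ", length(sn), " entries", call. = FALSE)
  }
  d <- drop(A %*% state)
  names(d) <- sn
  d
}

#' Simulate the PBK model
#'
#' Integrates the eight-compartment system over `time_grid`, applying each
#' dose event as an instantaneous state jump (see [apply_dose()]). The
#' default integrator is `deSolve`'s stiff-capable `lsoda` with the constant
#' analytic Jacobian; `solver = "rk4"` runs a fixed-step 4th-order explicit
#' integrator (step `rk4_step`) used as an independent numerical check.
#'
#' @param physiology A `species_physiology`.
#' @param params A `cell_kinetic_params`.
#' @param dose_events A single [dose_event()] or list of them.
#' @param time_grid Output times in hours, strictly increasing, starting at
#'   or before the first dose.
#' @param solver `"lsoda"` (default) or `"rk4"`.
#' @param rtol,atol Relative / absolute solver tolerances (lsoda). The
#'   absolute tolerance is in cells/L.
#' @param rk4_step Fixed step in hours for `solver = "rk4"`.
#' @return A `pbk_simulation` object: output `time` (h), `states` matrix
#'   (time x state), the inputs, and `dose_total`.
#' @examples
#' mouse <- load_species_physiology("mouse")
#' p <- load_kinetic_params("table1")
#' sim <- simulate_pbk(mouse, p, dose_event("intravenous", 5e5),
#'                     time_grid = seq(0, 24, by = 0.1))
#' survival_fraction(sim, 24)
#' @export
simulate_pbk <- function(physiology, params, dose_events,
                         time_grid = seq(0, 24, by = 0.05),
                         solver = c("lsoda", "rk4"),
                         rtol = 1e-8, atol = 1e-6, rk4_step = 1e-4) {
  solver <- match.arg(solver)
  if (inherits(dose_events, "dose_event")) dose_events <- list(dose_events)
  stopifnot(length(dose_events) >= 1)
  for (ev in dose_events) {
    if (!inherits(ev, "dose_event")) stop("dose_events must be dose_event objects",
                                          call. = FALSE)
  }
  time_grid <- as.numeric(time_grid)
  if (length(time_grid) < 2 || any(diff(time_grid) <= 0)) {
    stop("time_grid must be strictly increasing with at least 2 points",
         call. = FALSE)
  }
  ev_times <- vapply(dose_events, function(e) e$time, 0)
  if (min(ev_times) < time_grid[1]) {
    stop("time_grid must start at or before the first dose", call. = FALSE)
  }
  if (any(ev_times > max(time_grid))) {
    stop("dose event beyond the simulated range", call. = FALSE)
  }
  if (rtol <= 0 || atol <= 0) stop("solver tolerances must be positive",
                                   call. = FALSE)

  A <- build_rate_matrix(physiology, params)
  sn <- state_names()
  deriv <- function(t, y, parms) list(drop(parms %*% y))
  jac <- function(t, y, parms) parms

  # segment the grid at dose times; doses are instantaneous jumps
  seg_bounds <- sort(unique(c(time_grid[1], ev_times, max(time_grid))))
  y <- stats::setNames(numeric(length(sn)), sn)
  out_t <- numeric(0)
  out_y <- NULL
  for (s in seq_len(length(seg_bounds) - 1L)) {
    t0 <- seg_bounds[s]; t1 <- seg_bounds[s + 1L]
    for (ev in dose_events) if (ev$time == t0) y <- apply_dose(y, ev, physiology)
    tt <- unique(c(t0, time_grid[time_grid > t0 & time_grid <= t1], t1))
    if (length(tt) < 2) tt <- c(t0, t1)
    if (solver == "lsoda") {
      sol <- deSolve::lsoda(y, tt, deriv, parms = A, jacfunc = jac,
                            jactype = "fullusr", rtol = rtol, atol = atol)
    } else {
      steps <- seq(t0, t1, by = rk4_step)
      if (steps[length(steps)] < t1) steps <- c(steps, t1)
      full <- sort(unique(c(steps, tt)))
      sol <- deSolve::rk4(y, full, deriv, parms = A)
      sol <- sol[full %in% tt, , drop = FALSE]
    }
    ist <- attr(sol, "istate")
    if (!is.null(ist) && ist[1] < 0) {
      stop(sprintf("ODE solver failed on [%g, %g] h", t0, t1), call. = FALSE)
    }
    y <- stats::setNames(as.numeric(sol[nrow(sol), -1]), sn)
    keep <- which(sol[, 1] %in% time_grid)
    for (k in keep) {
      j <- match(sol[k, 1], out_t)
      if (is.na(j)) {                       # new output time
        out_t <- c(out_t, sol[k, 1])
        out_y <- rbind(out_y, sol[k, -1, drop = FALSE])
      } else {                              # dose boundary: keep post-dose state
        out_y[j, ] <- sol[k, -1]
      }
    }
  }
  states <- as.matrix(out_y)
  colnames(states) <- sn
  dose_total <- sum(vapply(dose_events, function(e) e$amount, 0))

  res <- structure(
    list(time = out_t, states = states, physiology = physiology,
         params = params, dose_events = dose_events, dose_total = dose_total,
         solver = solver),
    class = "pbk_simulation"
  )
  # guard: negative trajectories beyond tolerance indicate solver trouble
  if (dose_total > 0) {
    blood_vol <- physiology$arterial_blood_volume + physiology$venous_blood_volume
    if (min(states) < -1e-6 * dose_total / blood_vol) {
      warning("trajectory has negative entries beyond tolerance; tighten atol")
    }
  }
  res
}

interp_state <- function(result, column, t) {
  if (any(t < min(result$time)) || any(t > max(result$time))) {
    stop("time outside the simulated range", call. = FALSE)
  }
  stats::approx(result$time, result$states[, column], xout = t,
                ties = "ordered")$y
}

#' Survival fraction at a time point
#'
#' Fraction of the administered dose not yet eliminated through any
#' depletion route: `1 - D_cum(t) / dose`.
#'
#' @param result A `pbk_simulation`.
#' @param t Time(s) in hours within the simulated range.
#' @return Fraction in `[0, 1]`.
#' @export
survival_fraction <- function(result, t) {
  stopifnot(inherits(result, "pbk_simulation"))
  if (result$dose_total == 0) return(rep(1, length(t)))
  pmin(1, pmax(0, 1 - interp_state(result, "D_cum", t) / result$dose_total))
}

#' Amount of cells in a compartment at a time point
#'
#' For an organ: vascular amount `C_V * V_V` plus arrested amount `A_E`.
#' `"arterial_blood"` / `"venous_blood"` return the central pool amounts.
#'
#' @param result A `pbk_simulation`.
#' @param organ One of [PBK_ORGANS], `"arterial_blood"` or `"venous_blood"`.
#' @param t Time(s) in hours within the simulated range.
#' @return Amount in cells.
#' @export
amount_in_organ <- function(result, organ, t) {
  stopifnot(inherits(result, "pbk_simulation"))
  phys <- result$physiology
  if (organ == "arterial_blood") {
    return(interp_state(result, "C_arterial", t) * phys$arterial_blood_volume)
  }
  if (organ == "venous_blood") {
    return(interp_state(result, "C_venous", t) * phys$venous_blood_volume)
  }
  if (!organ %in% PBK_ORGANS) stop("unknown organ '", organ, "'", call. = FALSE)
  v <- organ_row(phys, organ)$vascular_volume
  interp_state(result, paste0("C_", organ), t) * v +
    interp_state(result, paste0("A_", organ), t)
}

#' Concentration per kg of tissue
#'
#' Observable concentration scale used for biodistribution data: organ
#' amount (vascular + arrested) divided by organ mass at density 1 kg/L.
#' `"blood"` maps to the venous pool concentration (cells/L = cells/kg at
#' unit density), matching terminal venous sampling.
#'
#' @param result A `pbk_simulation`.
#' @param compartment `"blood"` or one of [PBK_ORGANS].
#' @param t Time(s) in hours.
#' @return Concentration in cells/kg.
#' @export
concentration_per_kg <- function(result, compartment, t) {
  stopifnot(inherits(result, "pbk_simulation"))
  if (compartment == "blood") {
    return(interp_state(result, "C_venous", t))
  }
  if (!compartment %in% PBK_ORGANS) {
    stop("unknown compartment '", compartment, "'", call. = FALSE)
  }
  mass <- organ_row(result$physiology, compartment)$total_volume  # 1 kg/L
  amount_in_organ(result, compartment, t) / mass
}

#' Tidy data frame of a simulation
#'
#' One row per (time, compartment) with amount, concentration per L of
#' vascular space, concentration per kg of tissue, and the arrested amount.
#' Blood rows report the two central pools.
#'
#' @param x A `pbk_simulation`.
#' @param ... Unused.
#' @return A data frame with columns `time_h`, `compartment`,
#'   `amount_cells`, `concentration_cells_per_L`,
#'   `concentration_cells_per_kg`, `arrested_cells`.
#' @export
as.data.frame.pbk_simulation <- function(x, ...) {
  phys <- x$physiology
  out <- list()
  blood <- data.frame(
    compartment = rep(c("arterial_blood", "venous_blood"), each = length(x$time)),
    time_h = rep(x$time, 2),
    concentration_cells_per_L = c(x$states[, "C_arterial"], x$states[, "C_venous"]),
    arrested_cells = 0
  )
  blood$amount_cells <- blood$concentration_cells_per_L *
    rep(c(phys$arterial_blood_volume, phys$venous_blood_volume),
        each = length(x$time))
  blood$concentration_cells_per_kg <- blood$concentration_cells_per_L
  out[["blood"]] <- blood
  for (o in PBK_ORGANS) {
    row <- organ_row(phys, o)
    cv <- x$states[, paste0("C_", o)]
    ae <- x$states[, paste0("A_", o)]
    out[[o]] <- data.frame(
      compartment = o, time_h = x$time,
      concentration_cells_per_L = cv,
      arrested_cells = ae,
      amount_cells = cv * row$vascular_volume + ae,
      concentration_cells_per_kg = (cv * row$vascular_volume + ae) / row$total_volume
    )
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[, c("time_h", "compartment", "amount_cells", "concentration_cells_per_L",
         "concentration_cells_per_kg", "arrested_cells")]
}

#' Total live cells plus cumulative depleted, per output time
#'
#' Accounting series used by the conservation checks: should equal the
#' administered dose at every time after dosing.
#'
#' @param result A `pbk_simulation`.
#' @return Numeric vector along `result$time`.
#' @export
total_cell_balance <- function(result) {
  stopifnot(inherits(result, "pbk_simulation"))
  drop(result$states %*% mass_weights(result$physiology))
}

#' @export
print.pbk_simulation <- function(x, ...) {
  cat(sprintf("<pbk_simulation> %s, dose %.4g cells, t = [%g, %g] h (%d points, %s)\n",
              x$physiology$species, x$dose_total, min(x$time), max(x$time),
              length(x$time), x$solver))
  sf <- survival_fraction(x, max(x$time))
  cat(sprintf("  survival fraction at %g h: %.3f\n", max(x$time), sf))
  invisible(x)
}
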