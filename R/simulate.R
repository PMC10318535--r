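# Solver driver: stiff integration of the model with bolus dose events.

.NEG_TOL <- 1e-8  # relative negative-state tolerance before clipping

#' Simulate the tumor-immune model under a set of regimens
#'
#' Integrates the model with a stiff solver (lsoda via deSolve) using the
#' compiled right-hand side; doses are applied as instantaneous additions to
#' the central drug amount at their event times (the integrator restarts at
#' each event). Output is sampled on a regular grid plus all event times.
#' Solver output is verified non-negative to within a small tolerance and
#' clipped to zero.
#'
#' @param params a `qsp_params` parameter set.
#' @param regimens list of [regimen()] objects; empty list = no treatment.
#' @param init initial state (default [initial_state()]).
#' @param t_end simulation horizon in days (> 0).
#' @param dt output grid spacing (days).
#' @param rtol,atol solver tolerances.
#' @param use_compiled integrate the compiled C right-hand side (default);
#'   set `FALSE` to integrate the reference R implementation.
#' @return a `qsp_trajectory`: list with `time`, state `matrix` (rows =
#'   times), and derived channels `volume_cm3`, `diameter_cm`,
#'   `teff_density`, `treg_density`, `teff_treg_ratio` (tumor, cells/mL).
#' @export
simulate_model <- function(params, regimens = list(), init = NULL,
                           t_end = 400, dt = 1, rtol = 1e-6, atol = NULL,
                           use_compiled = TRUE) {
  if (t_end <= 0) stop("t_end must be > 0")
  if (inherits(regimens, "regimen")) regimens <- list(regimens)
  if (is.null(init)) init <- initial_state(params)
  y0 <- stats::setNames(as.numeric(init), .qsp_state_names)
  if (length(y0) != length(.qsp_state_names)) stop("bad initial state length")

  ev <- dose_events(regimens, params, t_end)
  times <- sort(unique(c(seq(0, t_end, by = dt), t_end, ev$time)))
  if (is.null(atol)) {
    # states span cells (1e0..1e12), mol (1e-12..) and M (1e-15..):
    # per-species absolute tolerances scaled to typical magnitudes
    scale <- rep(1e-3, length(y0))
    names(scale) <- .qsp_state_names
    scale[c("P_neo", "P_self", "A_C", "A_P", "A_T", "A_LN",
            "E_C", "E_P", "E_T", "E_LN")] <- 1e-18
    scale[c("CCL2", "ArgI", "NO", "TGFb")] <- 1e-18
    atol <- scale * 1e-6
  }

  if (use_compiled) {
    out <- deSolve::ode(y = y0, times = times, func = "qsp_deriv",
                        parms = pack_params(params), dllname = "qspio",
                        initfunc = "qsp_init", method = "lsoda",
                        rtol = rtol, atol = atol, events = list(data = ev),
                        maxsteps = 50000)
  } else {
    rhs <- function(t, y, parms) list(assemble_rhs(t, y, params))
    out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol,
                        events = list(data = ev), maxsteps = 50000)
  }
  if (attr(out, "istate")[1] < 0) {
    stop("solver failure at t = ", max(out[, "time"]))
  }
  m <- unclass(out)
  tt <- m[, 1]
  states <- m[, -1, drop = FALSE]
  neg <- states < 0
  if (any(neg)) {
    floor_ok <- -(.NEG_TOL * pmax(1, apply(abs(states), 2, max)))
    worst <- apply(states, 2, min)
    if (any(worst < floor_ok)) {
      bad <- colnames(states)[worst < floor_ok]
      stop("negative state beyond tolerance in: ", paste(bad, collapse = ", "))
    }
    states[neg] <- 0
  }
  new_trajectory(tt, states, params)
}

new_trajectory <- function(time, states, params) {
  geom <- tumor_volume_and_diameter(states[, "C"], params$rho_cell)
  V_mL <- pmax(states[, "C"] / params$rho_cell, 1e-4)  # tumor volume, mL
  traj <- list(time = time, states = states,
               volume_cm3 = geom$volume_cm3,
               diameter_cm = geom$diameter_cm,
               teff_density = states[, "Teff_T"] / V_mL,
               treg_density = states[, "Treg_T"] / V_mL,
               teff_treg_ratio = ifelse(states[, "Treg_T"] > 0,
                                        states[, "Teff_T"] / states[, "Treg_T"],
                                        NA_real_),
               params = params)
  class(traj) <- "qsp_trajectory"
  traj
}

#' @export
print.qsp_trajectory <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("QSP trajectory: %d time points over [%g, %g] days\n",
              n, min(x$time), max(x$time)))
  cat(sprintf("  tumor diameter: %.3f -> %.3f cm\n",
              x$diameter_cm[1], x$diameter_cm[n]))
  invisible(x)
}

#' Tidy data.frame view of a trajectory
#'
#' @param x a `qsp_trajectory`.
#' @param ... unused.
#' @return data.frame with `time`, every state column, `tumor_volume_cm3`
#'   and `tumor_diameter_cm`.
#' @export
as.data.frame.qsp_trajectory <- function(x, ...) {
  cbind(data.frame(time = x$time), as.data.frame(x$states),
        data.frame(tumor_volume_cm3 = x$volume_cm3,
                   tumor_diameter_cm = x$diameter_cm))
}

#' Grow an untreated tumor to its baseline diameter
#'
#' Simulates the drug-free system from seeding and stops at the first time
#' the tumor diameter crosses `target_d` (root-finding integrator, so the
#' returned state sits on the crossing). Failure to reach the target within
#' the horizon cap — growth stalled by immune control or carrying capacity —
#' is reported as a status, not an error, because cohort screening consumes
#' it.
#'
#' @param params a `qsp_params` parameter set.
#' @param target_d baseline diameter to reach (cm, > 0).
#' @param horizon_cap give-up horizon (days).
#' @return list with `status` (`"ok"` or `"non-patient: unreachable"`),
#'   `state` (model state at crossing, or `NULL`), `t_reach` (days), and
#'   `diameter_cm` actually attained.
#' @export
grow_to_baseline <- function(params, target_d, horizon_cap = 5000) {
  if (target_d <= 0) stop("target_d must be > 0")
  C_target <- diameter_to_cells(target_d, params$rho_cell)
  if (C_target >= params$C_max) {
    return(list(status = "non-patient: unreachable", state = NULL,
                t_reach = NA_real_, diameter_cm = NA_real_))
  }
  y0 <- initial_state(params)
  times <- seq(0, horizon_cap, by = 5)
  out <- deSolve::lsodar(y = stats::setNames(as.numeric(y0), .qsp_state_names),
                         times = times, func = "qsp_deriv",
                         parms = c(pack_params(params), C_target),
                         dllname = "qspio", initfunc = "qsp_init_root",
                         rootfunc = "qsp_root", nroot = 1,
                         rtol = 1e-6, atol = 1e-3, maxsteps = 50000)
  m <- unclass(out)
  last <- m[nrow(m), ]
  tt <- last[1]
  state <- pmax(last[-1], 0)
  names(state) <- .qsp_state_names
  d_att <- tumor_volume_and_diameter(state[["C"]], params$rho_cell)$diameter_cm
  if (abs(d_att - target_d) / target_d > 0.01) {
    return(list(status = "non-patient: unreachable", state = NULL,
                t_reach = NA_real_, diameter_cm = d_att))
  }
  list(status = "ok", state = state, t_reach = as.numeric(tt),
       diameter_cm = d_att)
}
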