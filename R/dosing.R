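# Dose regimens and four-compartment antibody pharmacokinetics.

#' Construct a dosing regimen
#'
#' @param drug `"apdl1"` (anti-PD-L1 antibody) or `"tce"` (T cell engager).
#' @param dose_mg dose per administration (mg, >= 0).
#' @param interval_days days between doses (e.g. 7/14/21 for QW/Q2W/Q3W).
#' @param start_day day of first dose (treatment time origin is day 0,
#'   the day the tumor reaches its baseline diameter).
#' @param end_day last day on which dosing may occur (default `Inf`: dose
#'   until the simulation horizon).
#' @return object of class `regimen`.
#' @export
regimen <- function(drug = c("apdl1", "tce"), dose_mg, interval_days = 7,
                    start_day = 0, end_day = Inf) {
  drug <- match.arg(drug)
  if (!is.finite(dose_mg) || dose_mg < 0) stop("dose_mg must be >= 0")
  if (interval_days <= 0) stop("interval_days must be > 0")
  if (start_day < 0) stop("start_day must be >= 0")
  if (end_day < start_day) stop("end_day must be >= start_day")
  structure(list(drug = drug, dose_mg = dose_mg,
                 interval_days = interval_days,
                 start_day = start_day, end_day = end_day),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("%s %g mg q%gd from day %g\n", x$drug, x$dose_mg,
              x$interval_days, x$start_day))
  invisible(x)
}

#' Expand a regimen into discrete dose events
#'
#' @param reg a [regimen()].
#' @param horizon simulation horizon (days, > 0); events strictly before
#'   `min(end_day, horizon)` are kept (a dose at the final instant cannot
#'   act within the simulated window).
#' @return data.frame with columns `time` (day), `drug`, `amount_mg`;
#'   zero rows for a zero-dose regimen.
#' @export
expand_regimen <- function(reg, horizon) {
  stopifnot(inherits(reg, "regimen"))
  if (horizon <= 0) stop("horizon must be > 0")
  if (reg$dose_mg < 0) stop("negative dose")
  if (reg$dose_mg == 0) {
    return(data.frame(time = numeric(0), drug = character(0),
                      amount_mg = numeric(0)))
  }
  stop_t <- min(reg$end_day, horizon)
  times <- seq(reg$start_day, by = reg$interval_days,
               length.out = max(0, ceiling((stop_t - reg$start_day) /
                                             reg$interval_days)))
  times <- times[times < stop_t]
  data.frame(time = times, drug = reg$drug,
             amount_mg = rep(reg$dose_mg, length(times)))
}

#' Convert a dose in mg to moles
#'
#' Applied as an instantaneous bolus to the central-compartment drug amount;
#' the concentration jump is `mg_to_moles(dose, MW) / V_C`.
#'
#' @param dose_mg dose (mg).
#' @param MW molecular weight (g/mol, > 0).
#' @return amount in mol.
#' @export
mg_to_moles <- function(dose_mg, MW) {
  if (any(MW <= 0)) stop("MW must be > 0")
  dose_mg * 1e-3 / MW
}

#' Per-drug PK parameters from a model parameter set
#'
#' @param params a `qsp_params` parameter set.
#' @param drug `"apdl1"` or `"tce"`.
#' @return named list: `CL`, `k_CP`, `k_PC`, `k_CT`, `k_TC`, `k_TLN`,
#'   `k_LNC`, `MW`.
#' @export
pk_params <- function(params, drug = c("apdl1", "tce")) {
  drug <- match.arg(drug)
  sfx <- if (drug == "apdl1") "_A" else "_E"
  g <- function(stem) params[[paste0(stem, sfx)]]
  list(CL = g("CL"), k_CP = g("k_CP"), k_PC = g("k_PC"), k_CT = g("k_CT"),
       k_TC = g("k_TC"), k_TLN = g("k_TLN"), k_LNC = g("k_LNC"), MW = g("MW"))
}

#' Four-compartment antibody PK derivatives
#'
#' Linear amount-based terms: clearance from central; bidirectional
#' central-peripheral and central-tumor exchange (tumor influx scaled by the
#' current tumor volume); unidirectional tumor-to-lymph-node lymphatic flow;
#' lymph node drainage back to central, which closes the mass balance.
#'
#' @param amounts numeric length-4 vector `(central, peripheral, tumor, ln)`
#'   in mol.
#' @param pk PK parameter list from [pk_params()].
#' @param V_T_cm3 current tumor volume (cm^3), scaling the central-to-tumor
#'   influx.
#' @return derivative vector (mol/day), same order.
#' @export
pk_rhs <- function(amounts, pk, V_T_cm3 = 1) {
  if (any(amounts < 0)) stop("drug amounts must be >= 0")
  A_C <- amounts[1]; A_P <- amounts[2]; A_T <- amounts[3]; A_LN <- amounts[4]
  in_T <- pk$k_CT * V_T_cm3 * A_C
  c(-pk$CL * A_C - pk$k_CP * A_C + pk$k_PC * A_P - in_T +
      pk$k_TC * A_T + pk$k_LNC * A_LN,
    pk$k_CP * A_C - pk$k_PC * A_P,
    in_T - pk$k_TC * A_T - pk$k_TLN * A_T,
    pk$k_TLN * A_T - pk$k_LNC * A_LN)
}

#' Build the solver event table for a set of regimens
#'
#' @param regimens list of [regimen()] objects (may be empty).
#' @param params a `qsp_params` parameter set (for molecular weights).
#' @param horizon simulation horizon (days).
#' @return data.frame in [deSolve::ode()] events format (`var`, `time`,
#'   `value` in mol, `method = "add"`), or `NULL` when no doses fall in the
#'   window.
#' @export
dose_events <- function(regimens, params, horizon) {
  if (length(regimens) == 0) return(NULL)
  ev <- do.call(rbind, lapply(regimens, expand_regimen, horizon = horizon))
  if (is.null(ev) || nrow(ev) == 0) return(NULL)
  var <- ifelse(ev$drug == "apdl1", "A_C", "E_C")
  MW <- ifelse(ev$drug == "apdl1", params$MW_A, params$MW_E)
  out <- data.frame(var = var, time = ev$time,
                    value = mg_to_moles(ev$amount_mg, MW),
                    method = "add", stringsAsFactors = FALSE)
  out[order(out$time), , drop = FALSE]
}
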