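# Virtual patient generation: Latin hypercube sampling over parameter
# ranges, physiological plausibility screening, and range calibration
# against clinical overall-response-rate targets.

#' Default sampled parameter ranges
#'
#' The subset of model parameters varied across virtual patients, with
#' sampling bounds, scale and provenance. The set mirrors the inputs of the
#' global sensitivity analysis: baseline tumor diameter, tumor growth rate,
#' neoantigen-specific clone number, kill rate, CEA and PD-L1 surface
#' densities, Treg-driven exhaustion, MDSC recruitment and the naive T cell
#' source. Ranges tagged `"calibrated"` have no experimentally reported
#' values and are adjusted by [calibrate_ranges()]; `"literature"` ranges
#' stay fixed. The inert `decoy` entry is carried as a negative control for
#' sensitivity analyses.
#'
#' @return data.frame of class `param_ranges` with columns `name`, `lower`,
#'   `upper`, `scale` ("linear" or "log"), `provenance`.
#' @export
default_ranges <- function() {
  r <- rbind(
    data.frame(name = "d_0",         lower = 2,    upper = 8,    scale = "linear", provenance = "literature"),
    data.frame(name = "k_growth",    lower = 5e-3, upper = 2.5e-2, scale = "log",  provenance = "literature"),
    data.frame(name = "TCC",         lower = 10,   upper = 1000, scale = "log",    provenance = "calibrated"),
    data.frame(name = "k_kill",      lower = 0.05, upper = 3,    scale = "log",    provenance = "calibrated"),
    data.frame(name = "CEA_per_C",   lower = 1e4,  upper = 1e6,  scale = "log",    provenance = "literature"),
    data.frame(name = "PDL1_per_C",  lower = 5e3,  upper = 5e5,  scale = "log",    provenance = "literature"),
    data.frame(name = "k_nT_source", lower = 3e7, upper = 2e8,  scale = "log",    provenance = "literature"),
    data.frame(name = "k_exh_Treg",  lower = 2e-2, upper = 0.5,  scale = "log",    provenance = "calibrated"),
    data.frame(name = "k_MDSC_rec",  lower = 1e4,  upper = 1e6,  scale = "log",    provenance = "literature"),
    data.frame(name = "decoy",       lower = 0,    upper = 1,    scale = "linear", provenance = "literature")
  )
  class(r) <- c("param_ranges", class(r))
  r
}

.validate_ranges <- function(ranges) {
  stopifnot(is.data.frame(ranges),
            all(c("name", "lower", "upper", "scale") %in% names(ranges)))
  if (any(ranges$lower >= ranges$upper)) {
    stop("invalid ranges: lower must be < upper")
  }
  if (any(ranges$scale == "log" & ranges$lower <= 0)) {
    stop("log-scaled ranges must be strictly positive")
  }
  invisible(ranges)
}

#' Latin hypercube sample of parameter overrides
#'
#' Stratified sampling: for each parameter exactly one draw falls in each of
#' the `N` equal-probability bins, in log space for log-scaled ranges.
#'
#' @param ranges a `param_ranges` table (see [default_ranges()]).
#' @param N number of virtual patients to draw.
#' @param seed integer seed; identical seeds give identical draws.
#' @return data.frame, one row per draw, one column per varied parameter.
#' @export
lhs_sample <- function(ranges, N, seed) {
  .validate_ranges(ranges)
  if (N < 1) stop("N must be >= 1")
  set.seed(seed)
  u <- lhs::randomLHS(N, nrow(ranges))
  out <- matrix(NA_real_, N, nrow(ranges))
  for (j in seq_len(nrow(ranges))) {
    lo <- ranges$lower[j]; hi <- ranges$upper[j]
    out[, j] <- if (ranges$scale[j] == "log") {
      exp(log(lo) + u[, j] * (log(hi) - log(lo)))
    } else {
      lo + u[, j] * (hi - lo)
    }
  }
  colnames(out) <- ranges$name
  as.data.frame(out)
}

#' Default plausibility screening windows
#'
#' @return list with `blood_T` (cells/mL window on total central T cell
#'   density), `teff_treg` (window on the baseline tumor Teff:Treg ratio),
#'   and `d_tol` (relative tolerance on reaching the target baseline
#'   diameter).
#' @export
default_screens <- function() {
  list(blood_T = c(3e5, 5e6), teff_treg = c(0.1, 50), d_tol = 0.01)
}

#' Screen one virtual patient candidate
#'
#' Applies the parameter overrides, grows the untreated tumor to the
#' patient's sampled baseline diameter, and checks the physiological
#' plausibility screens: target diameter reached, blood T cell density, and
#' baseline tumor Teff:Treg ratio. Every failure is a status, not an error.
#'
#' @param overrides named list/vector of sampled parameter values (entries
#'   not naming a model parameter, such as the decoy, are ignored for the
#'   simulation but kept for provenance).
#' @param params baseline `qsp_params` the overrides modify.
#' @param screens screening windows, see [default_screens()].
#' @return a `virtual_patient`: list with `overrides`, `status` ("accepted"
#'   or "non-patient:<reason>"), `state` (baseline state or NULL),
#'   `baseline_diameter`, `t_reach`, `blood_T`, `teff_treg`.
#' @export
screen_patient <- function(overrides, params = default_params(),
                           screens = default_screens()) {
  ov <- as.list(overrides)
  pat <- set_params(params, ov[names(ov) %in% names(params)])
  vp <- list(overrides = ov, status = NA_character_, state = NULL,
             baseline_diameter = NA_real_, t_reach = NA_real_,
             blood_T = NA_real_, teff_treg = NA_real_)
  class(vp) <- "virtual_patient"
  g <- grow_to_baseline(pat, pat$d_0)
  if (g$status != "ok") {
    vp$status <- "non-patient: unreachable"
    return(vp)
  }
  s <- g$state
  blood_T <- sum(s[c("nCD8_C", "nCD4_C", "Teff_C", "Th_C", "Treg_C")]) /
    (pat$V_C * 1000)
  ratio <- if (s[["Treg_T"]] > 0) s[["Teff_T"]] / s[["Treg_T"]] else Inf
  vp$baseline_diameter <- g$diameter_cm
  vp$t_reach <- g$t_reach
  vp$blood_T <- blood_T
  vp$teff_treg <- ratio
  if (blood_T < screens$blood_T[1] || blood_T > screens$blood_T[2]) {
    vp$status <- "non-patient: blood T cell density"
    return(vp)
  }
  if (ratio < screens$teff_treg[1] || ratio > screens$teff_treg[2]) {
    vp$status <- "non-patient: Teff:Treg ratio"
    return(vp)
  }
  vp$status <- "accepted"
  vp$state <- s
  vp
}

#' Generate a screened virtual patient cohort
#'
#' Draws `N` Latin-hypercube parameter sets and screens each candidate;
#' accepted and rejected candidates are both retained so that counts sum to
#' `N`. The same cohort object is reused across all treatment arms of a
#' virtual trial.
#'
#' @param ranges a `param_ranges` table.
#' @param N cohort size before screening.
#' @param seed integer seed (sampling is fully reproducible).
#' @param params baseline `qsp_params`.
#' @param screens screening windows.
#' @return a `qsp_cohort`: list with `patients` (accepted virtual patients),
#'   `rejected`, `ranges`, `params`, `screens`, `seed`, `N`.
#' @export
generate_cohort <- function(ranges = default_ranges(), N = 500, seed = 1,
                            params = default_params(),
                            screens = default_screens()) {
  draws <- lhs_sample(ranges, N, seed)
  vps <- lapply(seq_len(N), function(i) {
    screen_patient(as.list(draws[i, , drop = FALSE]), params, screens)
  })
  acc <- vps[vapply(vps, function(v) v$status == "accepted", logical(1))]
  rej <- vps[vapply(vps, function(v) v$status != "accepted", logical(1))]
  if (length(acc) == 0) {
    stop("no accepted virtual patients; recalibrate the parameter ranges")
  }
  structure(list(patients = acc, rejected = rej, ranges = ranges,
                 params = params, screens = screens, seed = seed, N = N),
            class = "qsp_cohort")
}

#' @export
print.qsp_cohort <- function(x, ...) {
  cat(sprintf("QSP virtual cohort: %d accepted / %d drawn (seed %s)\n",
              length(x$patients), x$N, format(x$seed)))
  reasons <- table(vapply(x$rejected, `[[`, "", "status"))
  if (length(reasons)) {
    for (nm in names(reasons)) cat(sprintf("  %s: %d\n", nm, reasons[[nm]]))
  }
  invisible(x)
}

#' Subsample the accepted patients of a cohort
#'
#' Used to run dose-grid and synergy-surface analyses at reduced cohort
#' size; sampling is seeded and without replacement.
#'
#' @param cohort a `qsp_cohort`.
#' @param n number of accepted patients to keep (capped at the available
#'   count).
#' @param seed integer seed.
#' @return the cohort with `patients` reduced to the subsample.
#' @export
subsample_cohort <- function(cohort, n, seed = 1) {
  n <- min(n, length(cohort$patients))
  set.seed(seed)
  cohort$patients <- cohort$patients[sort(sample.int(length(cohort$patients), n))]
  cohort
}

#' Calibrate unknown parameter ranges against clinical response rates
#'
#' Greedy coordinate search over the bounds of `"calibrated"`-tagged ranges:
#' a candidate range set is accepted when, for every clinical target, the
#' simulated cohort overall response rate falls inside the target's
#' confidence interval. Bounds are perturbed by multiplicative factors; each
#' evaluation regenerates the cohort (fixed seed) and simulates every target
#' regimen.
#'
#' @param ranges starting `param_ranges`.
#' @param clinical_targets list of targets, each a list with `regimens`
#'   (list of [regimen()]), `orr` (clinical ORR, percent) and `ci`
#'   (length-2 percent interval the simulated ORR must fall in).
#' @param budget maximum number of cohort evaluations.
#' @param N cohort size per evaluation.
#' @param seed seed for cohort generation (fixed across evaluations).
#' @param params baseline parameters.
#' @param screens screening windows.
#' @param factors multiplicative perturbation factors per bound.
#' @param horizon trial horizon (days).
#' @return list with `ranges` (calibrated), `achieved` (simulated ORR per
#'   target), `evaluations`, `trace` (search log), `success`.
#' @export
calibrate_ranges <- function(ranges, clinical_targets, budget = 20, N = 200,
                             seed = 20330, params = default_params(),
                             screens = default_screens(),
                             factors = c(1.25, 2, 0.8, 0.5), horizon = 400) {
  if (!length(clinical_targets)) stop("clinical_targets must be nonempty")
  .validate_ranges(ranges)

  evaluate <- function(rng) {
    cohort <- generate_cohort(rng, N = N, seed = seed, params = params,
                              screens = screens)
    orrs <- vapply(clinical_targets, function(tg) {
      run_trial(cohort, tg$regimens, horizon = horizon,
                bootstrap = FALSE)$orr
    }, numeric(1))
    miss <- vapply(seq_along(clinical_targets), function(i) {
      ci <- clinical_targets[[i]]$ci
      max(0, ci[1] - orrs[i], orrs[i] - ci[2])
    }, numeric(1))
    list(orrs = orrs, loss = sum(miss^2), ok = all(miss == 0))
  }

  trace <- list()
  used <- 0
  cur <- evaluate(ranges); used <- used + 1
  trace[[1]] <- c(eval = used, loss = cur$loss, cur$orrs)
  if (cur$ok) {
    return(list(ranges = ranges, achieved = cur$orrs, evaluations = used,
                trace = trace, success = TRUE))
  }

  cal_rows <- which(ranges$provenance == "calibrated")
  # kill rate is the most direct efficacy lever; explore it first, and
  # upper bounds (which move the responder tail) before lower bounds
  cal_rows <- cal_rows[order(ranges$name[cal_rows] != "k_kill")]
  best <- list(ranges = ranges, res = cur)
  repeat {
    improved <- FALSE
    for (row in cal_rows) {
      for (bound in c("upper", "lower")) {
        for (f in factors) {
          if (used >= budget) break
          cand <- best$ranges
          cand[row, bound] <- cand[row, bound] * f
          if (cand$lower[row] >= cand$upper[row]) next
          res <- try(evaluate(cand), silent = TRUE)
          used <- used + 1
          if (inherits(res, "try-error")) next
          trace[[length(trace) + 1]] <- c(eval = used, loss = res$loss, res$orrs)
          if (res$ok) {
            return(list(ranges = cand, achieved = res$orrs,
                        evaluations = used, trace = trace, success = TRUE))
          }
          if (res$loss < best$res$loss) {
            best <- list(ranges = cand, res = res)
            improved <- TRUE
          }
        }
        if (used >= budget) break
      }
      if (used >= budget) break
    }
    if (!improved || used >= budget) break
  }
  best_report <- list(ranges = best$ranges, achieved = best$res$orrs,
                      evaluations = used, trace = trace, success = FALSE)
  stop(structure(class = c("qspio_calibration_exhausted", "error",
                           "condition"),
                 list(message = paste0(
                   "calibration budget exhausted; best achieved ORRs: ",
                   paste(sprintf("%.1f%%", best$res$orrs), collapse = ", ")),
                   call = sys.call(-1), best = best_report)))
}
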