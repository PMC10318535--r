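# Virtual clinical trials: RECIST 1.1 scoring, ORR with bootstrap CIs,
# and the dose/schedule optimization grid.

#' Classify a tumor diameter series per RECIST 1.1
#'
#' Single-lesion scoring at scheduled assessment times: complete response
#' (CR) when the diameter falls below a measurability threshold; partial
#' response (PR) at >= 30% shrinkage from baseline; progressive disease
#' (PD) at >= 20% growth from the nadir together with an absolute increase
#' of at least 0.5 cm; stable disease (SD) otherwise. The best overall
#' response is the best category attained at any assessment (no
#' confirmation scan required).
#'
#' @param time assessment-capable time grid (days, starting at 0).
#' @param diameter tumor diameter (cm) at `time`; `diameter[1]` is the
#'   baseline.
#' @param assess_every days between scheduled assessments (first at
#'   `assess_every`).
#' @param cr_diameter diameter below which the lesion counts as resolved.
#' @return a `response_record`: list with `best_response` ("CR", "PR",
#'   "SD", "PD"), `best_change_pct`, `nadir_cm`, `baseline_cm`, and the
#'   per-assessment table `assessments`.
#' @export
classify_response <- function(time, diameter, assess_every = 56,
                              cr_diameter = 0.2) {
  if (!length(time) || !length(diameter)) stop("empty diameter series")
  if (length(time) != length(diameter)) stop("time/diameter length mismatch")
  baseline <- diameter[1]
  at <- seq(assess_every, max(time), by = assess_every)
  if (!length(at)) at <- max(time)
  d_at <- stats::approx(time, diameter, xout = at, rule = 2)$y
  cats <- character(length(at))
  nadir <- baseline
  for (i in seq_along(at)) {
    # nadir = smallest diameter observed up to this assessment (incl. baseline)
    upto <- diameter[time <= at[i]]
    nadir <- min(baseline, upto)
    d <- d_at[i]
    cats[i] <- if (d < cr_diameter) "CR"
    else if (d <= (1 - 0.30) * baseline) "PR"
    else if (d >= 1.20 * nadir && (d - nadir) >= 0.5) "PD"
    else "SD"
  }
  rank <- c(CR = 4, PR = 3, SD = 2, PD = 1)
  best <- names(rank)[match(max(rank[cats]), rank)]
  rec <- list(best_response = best,
              best_change_pct = 100 * (min(diameter) - baseline) / baseline,
              nadir_cm = min(diameter), baseline_cm = baseline,
              assessments = data.frame(time = at, diameter = d_at,
                                       category = cats))
  class(rec) <- "response_record"
  rec
}

#' Run one arm of a virtual clinical trial
#'
#' Simulates every accepted virtual patient under the given regimens from
#' its own baseline state, scores responses per RECIST 1.1, and summarizes
#' the arm: overall response rate (CR+PR fraction, percent), optional
#' bootstrap confidence interval, and the median/MAD percent-change trace.
#'
#' @param cohort a `qsp_cohort` with at least one accepted patient.
#' @param regimens list of [regimen()] objects (empty = untreated arm).
#' @param horizon trial horizon (days).
#' @param assess_every RECIST assessment interval (days).
#' @param bootstrap compute the bootstrap CI (see [bootstrap_orr_ci()]).
#' @param boot_k resample size (defaults to the number of patients).
#' @param boot_reps bootstrap replicates.
#' @param seed seed for the bootstrap resampling.
#' @return a `trial_result`: list with `regimens`, `records`,
#'   `diameters` (VP x time matrix), `time`, `orr`, `ci`, `n`,
#'   `median_change`, `mad_change`, `failed` (VP indices whose simulation
#'   errored, with reasons).
#' @export
run_trial <- function(cohort, regimens = list(), horizon = 400,
                      assess_every = 56, bootstrap = TRUE, boot_k = NULL,
                      boot_reps = 10000, seed = 1) {
  stopifnot(inherits(cohort, "qsp_cohort"))
  if (!length(cohort$patients)) stop("cohort has no accepted patients")
  if (inherits(regimens, "regimen")) regimens <- list(regimens)

  records <- list(); diam <- list(); failed <- list()
  tgrid <- NULL
  for (i in seq_along(cohort$patients)) {
    vp <- cohort$patients[[i]]
    ov <- vp$overrides
    pat <- set_params(cohort$params, ov[names(ov) %in% names(cohort$params)])
    tr <- try(simulate_model(pat, regimens, init = vp$state,
                             t_end = horizon), silent = TRUE)
    if (inherits(tr, "try-error")) {
      failed[[length(failed) + 1]] <- list(vp = i, reason = as.character(tr))
      next
    }
    keep <- tr$time %in% seq(0, horizon, by = 1)
    if (is.null(tgrid)) tgrid <- tr$time[keep]
    records[[length(records) + 1]] <-
      classify_response(tr$time, tr$diameter_cm, assess_every = assess_every)
    diam[[length(diam) + 1]] <- tr$diameter_cm[keep]
  }
  if (!length(records)) stop("all virtual patients failed to simulate")

  D <- do.call(rbind, diam)
  change <- 100 * sweep(D, 1, D[, 1], "/") - 100
  best <- vapply(records, `[[`, "", "best_response")
  n <- length(records)
  orr <- 100 * mean(best %in% c("CR", "PR"))
  ci <- NULL
  if (bootstrap) {
    k <- if (is.null(boot_k)) n else boot_k
    ci <- bootstrap_orr_ci(records, k = k, reps = boot_reps, seed = seed)
  }
  structure(list(regimens = regimens, records = records, diameters = D,
                 time = tgrid, orr = orr, ci = ci, n = n,
                 median_change = apply(change, 2, stats::median),
                 mad_change = apply(change, 2, stats::mad),
                 failed = failed),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  desc <- if (length(x$regimens)) {
    paste(vapply(x$regimens, function(r)
      sprintf("%s %gmg q%gd", r$drug, r$dose_mg, r$interval_days), ""),
      collapse = " + ")
  } else "untreated"
  cat(sprintf("Virtual trial arm [%s]: n = %d, ORR = %.1f%%", desc, x$n, x$orr))
  if (!is.null(x$ci)) {
    cat(sprintf(" (95%% CI %.1f%%-%.1f%%, bootstrap median %.1f%%)",
                x$ci[["lower"]], x$ci[["upper"]], x$ci[["median"]]))
  }
  cat("\n")
  print(table(factor(vapply(x$records, `[[`, "", "best_response"),
                     levels = c("CR", "PR", "SD", "PD"))))
  invisible(x)
}

#' Percentile bootstrap confidence interval for the ORR
#'
#' Resamples `k` response records with replacement `reps` times, computes
#' the ORR of each replicate, and returns the percentile interval and
#' bootstrap median, mirroring the comparison of simulated cohorts with
#' small clinical trial arms.
#'
#' @param records list of `response_record`s (or a logical responder
#'   vector).
#' @param k resample size (number of "patients" per replicate).
#' @param reps number of bootstrap replicates.
#' @param seed integer seed.
#' @return named numeric vector: `median`, `lower`, `upper` (percent).
#' @export
bootstrap_orr_ci <- function(records, k, reps = 10000, seed = 1) {
  if (!length(records)) stop("empty records")
  if (k < 1 || reps < 1) stop("k and reps must be >= 1")
  resp <- if (is.logical(records)) records else
    vapply(records, `[[`, "", "best_response") %in% c("CR", "PR")
  set.seed(seed)
  draws <- matrix(sample(resp, k * reps, replace = TRUE), nrow = reps)
  orrs <- 100 * rowMeans(draws)
  q <- stats::quantile(orrs, c(0.5, 0.025, 0.975), names = FALSE, type = 6)
  c(median = q[1], lower = q[2], upper = q[3])
}

#' Dose/schedule optimization grid
#'
#' Runs one virtual trial per combination of engager dose, engager interval
#' and anti-PD-L1 start day (anti-PD-L1 fixed at 1200 mg every 3 weeks),
#' reusing the same cohort in every cell, and reports the median tumor
#' volume at week 8 and the end-of-trial ORR.
#'
#' @param cohort a `qsp_cohort`.
#' @param tce_doses engager doses (mg; 0 = checkpoint monotherapy).
#' @param tce_intervals engager dosing intervals (days).
#' @param apdl1_starts anti-PD-L1 start days.
#' @param apdl1_dose,apdl1_interval fixed anti-PD-L1 dose (mg) and interval.
#' @param horizon trial horizon (days).
#' @return data.frame, one row per grid cell: `tce_dose_mg`,
#'   `tce_interval_days`, `apdl1_start_day`, `median_volume_wk8_cm3`,
#'   `orr_pct`.
#' @export
regimen_grid <- function(cohort, tce_doses, tce_intervals, apdl1_starts,
                         apdl1_dose = 1200, apdl1_interval = 21,
                         horizon = 400) {
  if (!length(tce_doses) || !length(tce_intervals) || !length(apdl1_starts)) {
    stop("empty grid")
  }
  grid <- expand.grid(tce_dose_mg = tce_doses,
                      tce_interval_days = tce_intervals,
                      apdl1_start_day = apdl1_starts,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    regs <- list(regimen("apdl1", apdl1_dose, apdl1_interval,
                         grid$apdl1_start_day[i]))
    if (grid$tce_dose_mg[i] > 0) {
      regs <- c(regs, list(regimen("tce", grid$tce_dose_mg[i],
                                   grid$tce_interval_days[i], 0)))
    }
    tr <- run_trial(cohort, regs, horizon = horizon, bootstrap = FALSE)
    wk8 <- which.min(abs(tr$time - 56))
    d_wk8 <- tr$diameters[, wk8]
    vol <- pi / 6 * d_wk8^3
    c(median_volume_wk8_cm3 = stats::median(vol), orr_pct = tr$orr)
  })
  cbind(grid, do.call(rbind, res))
}

#' Spider and waterfall export tables for a trial arm
#'
#' @param result a `trial_result`.
#' @return list with `spider` (long table: `vp`, `time`, `change_pct`, plus
#'   attribute rows for the median and MAD trace columns `median_change`,
#'   `mad_change`) and `waterfall` (per-VP best percent change, sorted
#'   descending, with the RECIST category).
#' @export
export_views <- function(result) {
  stopifnot(inherits(result, "trial_result"))
  if (!result$n) stop("empty trial result")
  D <- result$diameters
  change <- 100 * sweep(D, 1, D[, 1], "/") - 100
  spider <- data.frame(
    vp = rep(seq_len(nrow(D)), each = ncol(D)),
    time = rep(result$time, nrow(D)),
    change_pct = as.vector(t(change)))
  spider_summary <- data.frame(time = result$time,
                               median_change = result$median_change,
                               mad_change = result$mad_change)
  best <- vapply(result$records, `[[`, 0, "best_change_pct")
  cat_ <- vapply(result$records, `[[`, "", "best_response")
  ord <- order(best, decreasing = TRUE)
  list(spider = spider, spider_summary = spider_summary,
       waterfall = data.frame(vp = ord, best_change_pct = best[ord],
                              category = cat_[ord]))
}
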