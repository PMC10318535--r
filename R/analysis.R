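# Global sensitivity analysis (PRCC) and MuSyC drug-synergy fitting.

#' Partial rank correlation coefficients
#'
#' Rank-transforms the sampled parameter matrix and the outcome, then for
#' each parameter correlates the residuals of rank(x_j) and rank(y) after
#' linearly regressing both on the ranks of all other parameters. P-values
#' use the partial-correlation t transform.
#'
#' @param X N x P matrix or data.frame of sampled parameter values.
#' @param y length-N outcome vector.
#' @param df_method degrees of freedom for the t transform (default
#'   `N - P - 2`).
#' @return data.frame of class `prcc_result` with columns `name`, `prcc`,
#'   `p_value`, `rank` (by decreasing |PRCC|).
#' @export
prcc <- function(X, y, df_method = NULL) {
  X <- as.matrix(X)
  N <- nrow(X); P <- ncol(X)
  if (length(y) != N) stop("length(y) must equal nrow(X)")
  if (N <= P + 2) stop("need N > P + 2 samples")
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    stop("constant column(s): ",
         paste(colnames(X)[const], collapse = ", "))
  }
  if (stats::sd(y) == 0) stop("outcome is constant")
  R <- apply(X, 2, rank)
  ry <- rank(y)
  df <- if (is.null(df_method)) N - P - 2 else df_method
  out <- vapply(seq_len(P), function(j) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    rx_res <- stats::lm.fit(Z, R[, j])$residuals
    ry_res <- stats::lm.fit(Z, ry)$residuals
    r <- stats::cor(rx_res, ry_res)
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    c(r, 2 * stats::pt(-abs(tstat), df))
  }, numeric(2))
  res <- data.frame(name = colnames(X) %||% paste0("x", seq_len(P)),
                    prcc = out[1, ], p_value = out[2, ])
  res$rank <- rank(-abs(res$prcc), ties.method = "first")
  class(res) <- c("prcc_result", class(res))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tumor-size-ratio dose-response surface
#'
#' For every (engager dose, anti-PD-L1 dose) pair, simulates each accepted
#' virtual patient to the horizon and computes the ratio of final tumor
#' size under treatment to final tumor size untreated; the cell value is
#' the median ratio over patients. The (0, 0) cell is exactly 1 by
#' construction.
#'
#' @param cohort a `qsp_cohort`.
#' @param tce_doses engager dose grid (mg), including 0.
#' @param apdl1_doses anti-PD-L1 dose grid (mg), including 0.
#' @param horizon days to the size readout.
#' @param metric `"volume"` (default) or `"diameter"` tumor-size scale.
#' @param tce_interval,apdl1_interval dosing intervals (days).
#' @return a `dose_surface`: list with `tce_doses`, `apdl1_doses`, matrix
#'   `E` (rows = engager doses), `metric`.
#' @export
dose_response_surface <- function(cohort, tce_doses, apdl1_doses,
                                  horizon = 400,
                                  metric = c("volume", "diameter"),
                                  tce_interval = 7, apdl1_interval = 21) {
  metric <- match.arg(metric)
  if (!any(tce_doses == 0) || !any(apdl1_doses == 0)) {
    stop("dose grids must include 0")
  }
  size_of <- function(tr) {
    n <- length(tr$time)
    if (metric == "volume") tr$volume_cm3[n] else tr$diameter_cm[n]
  }
  final_size <- function(vp, regs) {
    ov <- vp$overrides
    pat <- set_params(cohort$params, ov[names(ov) %in% names(cohort$params)])
    size_of(simulate_model(pat, regs, init = vp$state, t_end = horizon))
  }
  untreated <- vapply(cohort$patients, final_size, numeric(1), regs = list())
  E <- matrix(NA_real_, length(tce_doses), length(apdl1_doses),
              dimnames = list(tce = tce_doses, apdl1 = apdl1_doses))
  for (i in seq_along(tce_doses)) {
    for (j in seq_along(apdl1_doses)) {
      if (tce_doses[i] == 0 && apdl1_doses[j] == 0) {
        E[i, j] <- 1
        next
      }
      regs <- list()
      if (tce_doses[i] > 0) {
        regs <- c(regs, list(regimen("tce", tce_doses[i], tce_interval, 0)))
      }
      if (apdl1_doses[j] > 0) {
        regs <- c(regs, list(regimen("apdl1", apdl1_doses[j],
                                     apdl1_interval, 0)))
      }
      treated <- vapply(cohort$patients, final_size, numeric(1), regs = regs)
      E[i, j] <- stats::median(treated / untreated)
    }
  }
  structure(list(tce_doses = tce_doses, apdl1_doses = apdl1_doses, E = E,
                 metric = metric),
            class = "dose_surface")
}

#' MuSyC two-drug Hill surface
#'
#' Evaluates the two-dimensional MuSyC Hill equation. Drug 1 potency is
#' rescaled by `alpha2` in the presence of drug 2 and vice versa
#' (`log(alpha) > 0` = synergistic potency); the combination's maximal
#' effect is `E3 = Emin_single - beta * (E0 - Emin_single)` where
#' `Emin_single = min(E1, E2)` (`beta > 0` = synergistic efficacy; effects
#' here decrease with benefit, e.g. tumor-size ratios).
#'
#' @param d1,d2 dose vectors/scalars (recycled).
#' @param par named list/vector with `E0`, `E1`, `E2`, `h1`, `h2`, `C1`,
#'   `C2`, `alpha1`, `alpha2`, `beta`.
#' @return effect values.
#' @export
musyc_effect <- function(d1, d2, par) {
  p <- as.list(par)
  t1 <- (d1 / p$C1)^p$h1
  t2 <- (d2 / p$C2)^p$h2
  Emin <- min(p$E1, p$E2)
  E3 <- Emin - p$beta * (p$E0 - Emin)
  w12 <- (p$alpha2^p$h1) * (p$alpha1^p$h2) * t1 * t2
  (p$E0 + t1 * p$E1 + t2 * p$E2 + w12 * E3) / (1 + t1 + t2 + w12)
}

#' Fit the MuSyC synergy model to a dose surface
#'
#' Least-squares fit of the two-dimensional MuSyC Hill surface
#' ([musyc_effect()]) by Levenberg-Marquardt with seeded multistart.
#' Positivity of `h1`, `h2`, `C1`, `C2`, `alpha1`, `alpha2` is enforced by
#' fitting on the log scale.
#'
#' @param surface a `dose_surface` (at least 4 x 4 including both
#'   single-drug edges).
#' @param n_starts number of multistart initializations.
#' @param seed seed for the start jitter.
#' @return a `synergy_fit`: list with the fitted parameters (`E0` ... as in
#'   [musyc_effect()]), `log_alpha1`, `log_alpha2`, `beta`, `residual_norm`,
#'   `converged`.
#' @export
fit_musyc <- function(surface, n_starts = 8, seed = 1) {
  stopifnot(inherits(surface, "dose_surface") || is.list(surface))
  E <- surface$E
  d1 <- surface$tce_doses; d2 <- surface$apdl1_doses
  if (length(d1) < 4 || length(d2) < 4) stop("surface must be at least 4x4")
  if (!any(d1 == 0) || !any(d2 == 0)) stop("both single-drug edges required")
  grid <- expand.grid(d1 = d1, d2 = d2)
  z <- as.vector(E)

  # log-alphas clamped to +/-5: one flat single-drug edge (a drug with no
  # median effect) otherwise leaves the potency shift unbounded
  unpack <- function(th) {
    list(E0 = th[1], E1 = th[2], E2 = th[3],
         h1 = exp(max(min(th[4], 1.7), -1.7)),
         h2 = exp(max(min(th[5], 1.7), -1.7)),
         C1 = exp(th[6]), C2 = exp(th[7]),
         alpha1 = exp(max(min(th[8], 5), -5)),
         alpha2 = exp(max(min(th[9], 5), -5)), beta = th[10])
  }
  # weak ridge on the log-alphas: the interaction weight only identifies
  # alpha1^h2 * alpha2^h1, so the minimum-norm (symmetric) split is taken,
  # and a surface with one flat edge cannot send a potency term diverging
  resid_fn <- function(th) {
    c(musyc_effect(grid$d1, grid$d2, unpack(th)) - z,
      sqrt(1e-3) * th[8:9])
  }
  E0_0 <- E[d1 == 0, d2 == 0]
  base <- c(E0_0, min(E[, d2 == 0]), min(E[d1 == 0, ]),
            0, 0, log(stats::median(d1[d1 > 0])),
            log(stats::median(d2[d2 > 0])), 0, 0, 0)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- base
    if (s > 1) {
      th0 <- th0 + c(stats::rnorm(3, 0, 0.05), stats::rnorm(4, 0, 0.5),
                     stats::rnorm(2, 0, 0.3), stats::rnorm(1, 0, 0.1))
    }
    fit <- try(minpack.lm::nls.lm(
      par = th0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 1000)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rn <- sqrt(sum(fit$fvec^2))
    if (!is.finite(rn)) next
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) stop("MuSyC fit failed to converge from any start")
  p <- unpack(best$fit$par)
  structure(c(p, list(log_alpha1 = log(p$alpha1), log_alpha2 = log(p$alpha2),
                      beta = p$beta, residual_norm = best$rn,
                      converged = best$fit$info %in% 1:4)),
            class = "synergy_fit")
}

#' @export
print.synergy_fit <- function(x, ...) {
  cat(sprintf(paste0("MuSyC fit: beta = %.3f, log(alpha1) = %.3f, ",
                     "log(alpha2) = %.3f (rss = %.2e)\n"),
              x$beta, x$log_alpha1, x$log_alpha2, x$residual_norm^2))
  invisible(x)
}
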