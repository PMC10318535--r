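# Pharmacodynamic binding algebra.
#
# Binding equilibrates fast relative to cellular dynamics, so ternary-complex
# formation and checkpoint occupancy are solved as algebraic quasi-steady
# states inside the ODE right-hand side rather than integrated as species.

#' Binding parameters from a model parameter set
#'
#' Collects the dissociation constants, receptor copy numbers, avidity factor
#' and activation-Hill constants used by the pharmacodynamic layer.
#'
#' @param params a `qsp_params` parameter set.
#' @return named list of binding parameters.
#' @export
binding_params <- function(params) {
  list(Kd_CD3 = params$Kd_CD3, Kd_CEA = params$Kd_CEA, chi = params$chi,
       CD3_per_T = params$CD3_per_T, CEA_per_C = params$CEA_per_C,
       Kd_PD1_PDL1 = params$Kd_PD1_PDL1, Kd_A_PDL1 = params$Kd_A_PDL1,
       PD1_per_T = params$PD1_per_T, PDL1_per_C = params$PDL1_per_C,
       PDL1_per_Treg = params$PDL1_per_Treg,
       f_syn = params$f_syn, K_syn = params$K_syn, n_syn = params$n_syn,
       K_PD1 = params$K_PD1, n_PD1 = params$n_PD1)
}

# Positive root of a*x^2 + b*x + c = 0 with a >= 0, c <= 0, numerically stable
.pos_quad_root <- function(a, b, c) {
  if (a == 0) {
    if (b == 0) return(0)
    return(-c / b)
  }
  disc <- b * b - 4 * a * c
  s <- sqrt(max(disc, 0))
  if (b <= 0) (-b + s) / (2 * a) else -2 * c / (b + s)
}

#' Trimolecular engager binding at quasi-steady state
#'
#' Solves the two-step binding network of a bispecific T cell engager E with
#' CD3 (on T cells) and CEA (on cancer cells):
#' E + CD3 = E.CD3 (Kd `Kd_CD3`), E + CEA = E.CEA (Kd `Kd_CEA`), and either
#' binary complex plus the second target forms the ternary synapse
#' CEA.E.CD3 with the second event's affinity multiplied by the avidity
#' factor `chi`. Totals of E, CD3 and CEA are conserved. The free-engager
#' concentration is found by a monotone scalar root solve; at fixed free E
#' the remaining network reduces to a quadratic.
#'
#' @param E_tot,CD3_tot,CEA_tot total molar concentrations (M).
#' @param bp binding parameter list from [binding_params()].
#' @param tol relative tolerance of the root solve.
#' @return list with free species `e`, `c3`, `cea`, binary complexes `b3`
#'   (E.CD3), `bC` (E.CEA) and the ternary complex `ternary` (all M).
#' @export
ternary_complex_qss <- function(E_tot, CD3_tot, CEA_tot, bp, tol = 1e-12) {
  if (any(c(E_tot, CD3_tot, CEA_tot) < 0)) stop("totals must be >= 0")
  K3 <- bp$Kd_CD3; KC <- bp$Kd_CEA; chi <- bp$chi
  if (E_tot == 0 || (CD3_tot == 0 && CEA_tot == 0)) {
    return(list(e = E_tot, c3 = CD3_tot, cea = CEA_tot,
                b3 = 0, bC = 0, ternary = 0))
  }
  inner <- function(e) {
    u <- e / K3; v <- e / KC; w <- e * chi / (K3 * KC)
    a <- w * (1 + v)
    b <- (1 + v) * (1 + u) + w * (CD3_tot - CEA_tot)
    cc <- -CEA_tot * (1 + u)
    cea <- .pos_quad_root(a, b, cc)
    c3 <- CD3_tot / (1 + u + w * cea)
    list(c3 = c3, cea = cea, tern = w * c3 * cea)
  }
  g <- function(e) {
    s <- inner(e)
    e * (1 + s$c3 / K3 + s$cea / KC) + s$tern - E_tot
  }
  sol <- stats::uniroot(g, interval = c(0, E_tot), tol = tol * E_tot,
                        f.lower = -E_tot, maxiter = 2000)
  e <- sol$root
  s <- inner(e)
  res <- list(e = e, c3 = s$c3, cea = s$cea,
              b3 = e * s$c3 / K3, bC = e * s$cea / KC, ternary = s$tern)
  # conservation check doubles as the convergence diagnostic
  etot <- res$e + res$b3 + res$bC + res$ternary
  if (abs(etot - E_tot) > 1e-6 * max(E_tot, .Machine$double.xmin)) {
    stop("ternary QSS solve did not conserve engager (residual ",
         format(etot - E_tot), ")")
  }
  res
}

#' Synapses per T cell from engager binding
#'
#' Converts tumor-interstitium concentrations of engager, CEA and CD3 into
#' the expected number of productive cytolytic synapses per T cell: the
#' quasi-steady-state ternary complex per cell scaled by the
#' productive-synapse fraction. Exhibits the bell-shaped (hook) dose
#' dependence: excess engager saturates each target separately and depletes
#' ternary complexes.
#'
#' @param E_T engager concentration in the tumor interstitium (M).
#' @param CEA_tot,CD3_tot total target concentrations (M).
#' @param bp binding parameter list from [binding_params()].
#' @return synapses per T cell (count, >= 0); 0 when any input is 0.
#' @export
synapse_per_tcell <- function(E_T, CEA_tot, CD3_tot, bp) {
  if (any(c(E_T, CEA_tot, CD3_tot) < 0)) stop("inputs must be >= 0")
  if (E_T == 0 || CEA_tot == 0 || CD3_tot == 0) return(0)
  qss <- ternary_complex_qss(E_T, CD3_tot, CEA_tot, bp)
  bp$f_syn * bp$CD3_per_T * qss$ternary / CD3_tot
}

#' Synapse-driven T cell activation multiplier
#'
#' Hill function of synapses per T cell; calibrated against synapse-vs-
#' activation data by [fit_activation_hill()]. Feeds the kill-rate boost
#' `beta_max * activation_multiplier(...)`.
#'
#' @param syn synapses per T cell (>= 0, vectorized).
#' @param K_syn,n_syn Hill half-max and exponent.
#' @return activation fraction in `[0, 1]`.
#' @export
activation_multiplier <- function(syn, K_syn, n_syn) {
  hill(syn, K_syn, n_syn)
}

#' Fit the activation Hill function to synapse/activation data
#'
#' Weighted least-squares fit of `hill(syn, K, n)` to measured activation
#' fractions, on log-transformed parameters to enforce positivity.
#'
#' @param data data.frame with columns `synapses` and `activation`
#'   (fractions in `[0, 1]`); at least 4 points.
#' @param weights optional per-point weights (default equal).
#' @param start optional named start values `c(K_syn=, n_syn=)`.
#' @return list with `K_syn`, `n_syn`, `residual_norm`, `converged`, and the
#'   `fit` object from [minpack.lm::nls.lm()].
#' @export
fit_activation_hill <- function(data, weights = NULL, start = NULL) {
  stopifnot(is.data.frame(data), all(c("synapses", "activation") %in% names(data)))
  x <- data$synapses; y <- data$activation
  if (length(x) < 4) stop("need at least 4 points")
  if (any(y < 0 | y > 1)) stop("activation values must lie in [0, 1]")
  if (stats::sd(y) < 1e-12 || stats::sd(x) < 1e-12) {
    stop("unidentifiable: activation or synapse values are degenerate")
  }
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  if (is.null(start)) {
    ymax <- max(y)
    K0 <- x[which.min(abs(y - ymax / 2))]
    if (K0 <= 0) K0 <- stats::median(x[x > 0])
    start <- c(K_syn = K0, n_syn = 1)
  }
  resid_fn <- function(lp) {
    sqrt(w) * (hill(x, exp(lp[1]), exp(lp[2])) - y)
  }
  fit <- minpack.lm::nls.lm(par = log(c(start[["K_syn"]], start[["n_syn"]])),
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- exp(fit$par)
  list(K_syn = est[1], n_syn = est[2],
       residual_norm = sqrt(sum(fit$fvec^2)),
       converged = fit$info %in% 1:4,
       fit = fit)
}

#' PD-1 occupancy under anti-PD-L1 competition
#'
#' Competitive binding equilibrium on the PD-L1 axis: the anti-PD-L1
#' antibody sequesters PD-L1 (Kd `Kd_A_PDL1`); the remaining free PD-L1
#' engages PD-1 (Kd `Kd_PD1_PDL1`). PD-1 and PD-L1 totals are conserved;
#' the antibody is treated as buffered at its free interstitial
#' concentration, since the tumor pool exchanges continuously with the much
#' larger systemic reservoir. The equilibrium then reduces to a quadratic
#' in free PD-L1. Returns the fraction of PD-1 bound by PD-L1 — the
#' inhibitory signal the checkpoint Hill transforms — monotone decreasing
#' in the drug concentration.
#'
#' @param A_T free anti-PD-L1 concentration in the tumor interstitium (M).
#' @param PD1_tot,PDL1_tot total receptor concentrations (M).
#' @param bp binding parameter list from [binding_params()].
#' @return fraction of PD-1 occupied by PD-L1, in `[0, 1]`.
#' @export
pd1_occupancy <- function(A_T, PD1_tot, PDL1_tot, bp) {
  if (any(c(A_T, PD1_tot, PDL1_tot) < 0)) stop("inputs must be >= 0")
  if (PDL1_tot == 0 || PD1_tot == 0) return(0)
  Kd1 <- bp$Kd_PD1_PDL1; KdA <- bp$Kd_A_PDL1
  # free PD-L1 L solves a*L^2 + (a*Kd1 + PD1_tot - PDL1_tot)*L
  #   - PDL1_tot*Kd1 = 0 with a = 1 + A_T/KdA
  a <- 1 + A_T / KdA
  L <- .pos_quad_root(a, a * Kd1 + PD1_tot - PDL1_tot, -PDL1_tot * Kd1)
  (L / Kd1) / (1 + L / Kd1)
}
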