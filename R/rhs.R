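# Reduced tumor-immune ODE right-hand side (reference implementation).
#
# The solver driver normally integrates a compiled C copy of this function
# (src/qsp_rhs.c) for speed; the two are asserted equal in the test suite.

#' Tumor-cell killing rate by effector T cells
#'
#' Killing depends on the effector-to-cancer cell ratio through a Hill term,
#' is boosted by engager-formed synapses, and is attenuated by checkpoint
#' signaling (PD-1 occupancy Hill) and by the combined Arg-I/NO/Treg
#' suppression fraction.
#'
#' @param state named model state vector (needs `C` and `Teff_T`).
#' @param params a `qsp_params` parameter set.
#' @param H_PD1 PD-1 occupancy fraction in `[0, 1]` (from
#'   [pd1_occupancy()]).
#' @param synapse_boost non-negative kill multiplier addend
#'   (`beta_max * activation_multiplier(...)`).
#' @param suppression combined suppression fraction in `[0, 1]`.
#' @return kill rate in cells/day; 0 when either cell population is 0.
#' @export
killing_rate <- function(state, params, H_PD1, synapse_boost, suppression) {
  C <- state[["C"]]; Teff <- state[["Teff_T"]]
  if (C < 0 || Teff < 0) stop("negative state components")
  if (!all(is.finite(c(H_PD1, synapse_boost, suppression)))) {
    stop("non-finite killing inputs")
  }
  if (H_PD1 < 0 || H_PD1 > 1 || suppression < 0 || suppression > 1 ||
      synapse_boost < 0) {
    stop("killing inputs out of range")
  }
  if (C == 0 || Teff == 0) return(0)
  inh <- hill(H_PD1, params$K_PD1, params$n_PD1)
  params$k_kill * C * hill(Teff / C, params$K_ratio, params$n_ratio) *
    (1 + synapse_boost) * (1 - inh) * (1 - suppression)
}

# Pharmacodynamic quantities at a given state (shared by RHS and reporting)
.pd_signals <- function(state, params) {
  bp <- binding_params(params)
  C <- max(state[["C"]], 0); Teff <- max(state[["Teff_T"]], 0)
  Treg <- max(state[["Treg_T"]], 0)
  V_int <- .tumor_volume_L(C, params) * params$f_int
  molar <- function(copies) copies / (.N_AVOGADRO * V_int)
  E_T <- max(state[["E_T"]], 0) / V_int
  A_T <- max(state[["A_T"]], 0) / V_int
  CD3_tot <- molar(params$CD3_per_T * Teff)
  CEA_tot <- molar(params$CEA_per_C * C)
  PD1_tot <- molar(params$PD1_per_T * Teff)
  PDL1_tot <- molar(params$PDL1_per_C * C + params$PDL1_per_Treg * Treg)
  syn <- synapse_per_tcell(E_T, CEA_tot, CD3_tot, bp)
  act <- activation_multiplier(syn, params$K_syn, params$n_syn)
  H_PD1 <- pd1_occupancy(A_T, PD1_tot, PDL1_tot, bp)
  list(syn = syn, act = act, H_PD1 = H_PD1,
       kill_boost = params$use_kill_boost * params$beta_max * act,
       prolif_boost = params$use_prolif_boost * params$beta_prolif * act)
}

#' Assemble the model derivative vector
#'
#' The full reduced tumor-immune right-hand side: logistic tumor growth with
#' first-order apoptosis and ratio-dependent immune killing; antigen release
#' proportional to cancer cell death; APC uptake, maturation and migration;
#' naive T cell sourcing, death and trafficking (central/peripheral/lymph
#' node); antigen-driven activation in the lymph node scaled by the
#' neoantigen-specific clone number; activated-T proliferation and egress;
#' tumor infiltration; PD-1- and Treg-driven exhaustion; CCL2-driven MDSC
#' recruitment; Arg-I/NO/TGF-beta secretion and clearance; TGF-beta+Arg-I
#' driven Th-to-Treg trans-differentiation; and linear four-compartment PK
#' for both antibodies.
#'
#' @param t time (day); the autonomous system ignores it except for event
#'   handling by the driver.
#' @param state named state vector in [state_names()] order.
#' @param params a `qsp_params` parameter set.
#' @return named derivative vector, same length and order as `state`.
#' @export
assemble_rhs <- function(t, state, params) {
  if (length(state) != length(.qsp_state_names)) {
    stop("state length does not match the model build")
  }
  s <- stats::setNames(as.numeric(state), .qsp_state_names)
  if (any(s < -1e-6 * max(1, abs(s)))) {
    stop("negative state beyond tolerance at t=", t)
  }
  s <- pmax(s, 0)
  p <- params

  pd <- .pd_signals(s, p)
  supp <- 1 -
    (1 - hill(s[["ArgI"]], p$K_ArgI, 1)) *
    (1 - hill(s[["NO"]], p$K_NO, 1)) *
    (1 - hill(s[["Treg_T"]], p$K_Treg_supp, 1))
  R_kill <- killing_rate(s, p, pd$H_PD1, pd$kill_boost, supp)
  inh <- hill(pd$H_PD1, p$K_PD1, p$n_PD1)

  d <- stats::setNames(numeric(length(s)), names(s))
  C <- s[["C"]]

  # tumor
  d[["C"]] <- p$k_growth * C * (1 - C / p$C_max) - p$k_apop * C - R_kill

  # antigen release and APC handling
  release <- p$k_apop * C + R_kill
  for (ag in c("P_neo", "P_self")) {
    a <- if (ag == "P_neo") p$a_neo else p$a_self
    d[[ag]] <- a * release - p$k_P_deg * s[[ag]] - p$k_up * s[["APC"]] * s[[ag]]
  }
  mat <- p$k_mat * s[["APC"]] * hill(s[["P_neo"]] + s[["P_self"]], p$K_P, 1)
  d[["APC"]] <- p$k_APC0 * (p$APC_base - s[["APC"]]) - mat
  d[["mAPC"]] <- mat - (p$k_mAPC_mig + p$k_APC_death) * s[["mAPC"]]
  d[["mAPC_LN"]] <- p$k_mAPC_mig * s[["mAPC"]] - p$k_APC_death * s[["mAPC_LN"]]

  # naive T trafficking and activation
  drive <- hill(s[["mAPC_LN"]], p$K_act, p$n_act)
  act_scale <- c(nCD8 = p$TCC / p$TCC_ref, nCD4 = 1)
  act_flux <- numeric(2); names(act_flux) <- c("nCD8", "nCD4")
  for (lin in c("nCD8", "nCD4")) {
    nC <- s[[paste0(lin, "_C")]]; nP <- s[[paste0(lin, "_P")]]
    nLN <- s[[paste0(lin, "_LN")]]
    act_flux[lin] <- p$k_act * nLN * drive * act_scale[[lin]]
    d[[paste0(lin, "_C")]] <- p$k_nT_source - p$k_nT_death * nC -
      p$k_CP * nC + p$k_PC * nP - p$k_CLN * nC + p$k_LNC * nLN
    d[[paste0(lin, "_P")]] <- p$k_CP * nC - (p$k_PC + p$k_nT_death) * nP
    d[[paste0(lin, "_LN")]] <- p$k_CLN * nC - (p$k_LNC + p$k_nT_death) * nLN -
      act_flux[lin]
  }

  # activated T cells in the lymph node
  a8 <- s[["aCD8_LN"]]; a4 <- s[["aCD4_LN"]]
  room <- max(0, 1 - (a8 + a4) / p$aT_max)
  prolif <- p$k_aT_prolif * (1 + pd$prolif_boost) * room
  d[["aCD8_LN"]] <- act_flux[["nCD8"]] + prolif * a8 - p$k_aT_exit * a8
  d[["aCD4_LN"]] <- act_flux[["nCD4"]] + prolif * a4 - p$k_aT_exit * a4

  # central effector pools and tumor infiltration
  f_inf <- hill(C, p$K_C_inf, 1)
  inflow <- c(Teff = p$k_aT_exit * a8,
              Th = (1 - p$f_Treg) * p$k_aT_exit * a4,
              Treg = p$f_Treg * p$k_aT_exit * a4)
  infil <- numeric(3); names(infil) <- names(inflow)
  for (ct in names(inflow)) {
    cc <- s[[paste0(ct, "_C")]]
    infil[ct] <- p$k_infil * cc * f_inf
    d[[paste0(ct, "_C")]] <- inflow[[ct]] - p$k_Teff_death_C * cc - infil[ct]
  }

  # tumor-infiltrating T cells
  exh <- p$k_exh_PD1 * s[["Teff_T"]] * inh +
    p$k_exh_Treg * s[["Teff_T"]] * hill(s[["Treg_T"]], p$K_Treg_exh, 1)
  trans <- p$k_ThTreg * s[["Th_T"]] * hill(s[["TGFb"]], p$K_TGFb, 1) *
    hill(s[["ArgI"]], p$K_ArgI_td, 1)
  d[["Teff_T"]] <- infil[["Teff"]] - p$k_Teff_death_T * s[["Teff_T"]] - exh
  d[["Th_T"]] <- infil[["Th"]] - p$k_Teff_death_T * s[["Th_T"]] - trans
  d[["Treg_T"]] <- infil[["Treg"]] + trans - p$k_Teff_death_T * s[["Treg_T"]]
  d[["Texh_T"]] <- exh - p$k_Texh_death * s[["Texh_T"]]

  # MDSC and soluble mediators
  d[["MDSC_T"]] <- p$k_MDSC_rec * hill(s[["CCL2"]], p$K_CCL2, 1) *
    max(0, 1 - s[["MDSC_T"]] / p$MDSC_max) - p$k_MDSC_death * s[["MDSC_T"]]
  V_T <- .tumor_volume_L(C, p)
  d[["CCL2"]] <- p$k_CCL2_sec * C / V_T - p$k_CCL2_deg * s[["CCL2"]]
  d[["ArgI"]] <- p$k_ArgI_sec * s[["MDSC_T"]] / V_T - p$k_ArgI_deg * s[["ArgI"]]
  d[["NO"]] <- p$k_NO_sec * s[["MDSC_T"]] / V_T - p$k_NO_deg * s[["NO"]]
  d[["TGFb"]] <- p$k_TGFb_sec * s[["Treg_T"]] / V_T - p$k_TGFb_deg * s[["TGFb"]]

  # antibody PK
  V_T_cm3 <- V_T * 1000
  dA <- pk_rhs(s[c("A_C", "A_P", "A_T", "A_LN")], pk_params(p, "apdl1"), V_T_cm3)
  dE <- pk_rhs(s[c("E_C", "E_P", "E_T", "E_LN")], pk_params(p, "tce"), V_T_cm3)
  d[c("A_C", "A_P", "A_T", "A_LN")] <- dA
  d[c("E_C", "E_P", "E_T", "E_LN")] <- dE

  if (any(!is.finite(d))) {
    stop("non-finite derivative in term(s): ",
         paste(names(d)[!is.finite(d)], collapse = ", "))
  }
  d
}
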