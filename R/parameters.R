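#' @useDynLib qspio, .registration = TRUE
NULL

# Avogadro's number (1/mol)
.N_AVOGADRO <- 6.02214076e23

# Parameter table: name, default, unit, brief role.  This is the single
# source of truth; the packed numeric vector handed to the compiled RHS
# follows exactly this row order.
.qsp_par_table <- function() {
  # nolint start: line_length
  tab <- rbind(
    # --- geometry / global -------------------------------------------------
    c("V_C",          "5",       "L",            "central (blood) compartment volume"),
    c("V_P",          "60",      "L",            "peripheral compartment volume"),
    c("V_LN",         "5e-4",    "L",            "tumor-draining lymph node volume"),
    c("rho_cell",     "1e9",     "cells/cm^3",   "cancer cell packing density"),
    c("f_int",        "0.55",    "1",            "tumor interstitial volume fraction"),
    c("C_seed",       "1e6",     "cells",        "cancer cell count at tumor seeding"),
    c("d_0",          "5",       "cm",           "target pre-treatment tumor diameter"),
    c("C_max",        "1e12",    "cells",        "logistic carrying capacity"),
    # --- tumor growth / killing -------------------------------------------
    c("k_growth",     "0.012",   "1/day",        "logistic tumor growth rate"),
    c("k_apop",       "0.001",   "1/day",        "first-order cancer apoptosis rate"),
    c("k_kill",       "0.12",     "1/day",        "maximal T-cell kill rate"),
    c("K_ratio",      "0.1",     "1",            "half-max of Teff:cancer ratio in kill Hill"),
    c("n_ratio",      "1",     "1",            "Hill exponent of kill ratio term"),
    # --- antigen ----------------------------------------------------------
    c("a_neo",        "1e-18",   "mol/cell",     "neoantigen released per dying cell"),
    c("a_self",       "5e-18",   "mol/cell",     "self antigen released per dying cell"),
    c("k_P_deg",      "1",       "1/day",        "free antigen degradation rate"),
    c("k_up",         "1e-7",    "1/cell/day",   "antigen uptake rate per APC"),
    # --- APC --------------------------------------------------------------
    c("APC_base",     "1e5",     "cells",        "resting immature APC pool in tumor"),
    c("k_APC0",       "0.1",     "1/day",        "APC pool relaxation rate"),
    c("k_mat",        "1",       "1/day",        "APC maturation rate (antigen-driven)"),
    c("K_P",          "1e-11",   "mol",          "antigen half-max for APC maturation"),
    c("k_mAPC_mig",   "0.2",     "1/day",        "mature APC migration to lymph node"),
    c("k_APC_death",  "0.02",    "1/day",        "mature APC death rate"),
    # --- naive T cells ----------------------------------------------------
    c("k_nT_source",  "8e7",   "cells/day",    "thymic naive T source per lineage (central)"),
    c("k_nT_death",   "0.01",    "1/day",        "naive T death rate"),
    c("k_CP",         "0.1",     "1/day",        "naive T central->peripheral rate"),
    c("k_PC",         "0.05",    "1/day",        "naive T peripheral->central rate"),
    c("k_CLN",        "0.002",   "1/day",        "naive T central->lymph node entry"),
    c("k_LNC",        "0.2",     "1/day",        "naive T lymph node->central exit"),
    # --- activation in the lymph node -------------------------------------
    c("k_act",        "4",       "1/day",        "maximal naive T activation rate"),
    c("K_act",        "2e4",     "cells",        "mature-APC drive half-max for activation"),
    c("n_act",        "2",       "1",            "Hill exponent of activation drive"),
    c("TCC",          "80",      "1",            "neoantigen-specific T cell clone number"),
    c("TCC_ref",      "100",     "1",            "clone number giving unit CD8 activation scale"),
    c("k_aT_prolif",  "0.3",     "1/day",        "activated T proliferation rate in LN"),
    c("aT_max",       "5e9",    "cells",        "activated T carrying capacity in LN"),
    c("k_aT_exit",    "0.5",     "1/day",        "activated T egress to central"),
    c("f_Treg",       "0.15",    "1",            "fraction of activated CD4 becoming Treg"),
    # --- effector/helper/regulatory dynamics ------------------------------
    c("k_Teff_death_C", "0.05",  "1/day",        "effector death rate in central"),
    c("k_Teff_death_T", "0.1",   "1/day",        "effector death rate in tumor"),
    c("k_infil",      "0.12",    "1/day",        "tumor infiltration rate of central effectors"),
    c("K_C_inf",      "5e10",     "cells",        "tumor size half-max for infiltration"),
    c("k_exh_PD1",    "0.1",     "1/day",        "PD-1 driven Teff exhaustion rate"),
    c("k_exh_Treg",   "0.1",     "1/day",        "Treg driven Teff exhaustion rate"),
    c("K_Treg_exh",   "5e6",     "cells",        "Treg half-max for exhaustion"),
    c("k_Texh_death", "0.05",    "1/day",        "exhausted T death rate"),
    c("k_ThTreg",     "0.1",     "1/day",        "Th->Treg trans-differentiation rate"),
    c("K_TGFb",       "1e-11",   "M",            "TGF-beta half-max for trans-differentiation"),
    c("K_ArgI_td",    "1e-8",    "M",            "Arg-I half-max for trans-differentiation"),
    # --- suppression half-maxes -------------------------------------------
    c("K_ArgI",       "5e-8",    "M",            "Arg-I half-max for cytotoxicity inhibition"),
    c("K_NO",         "1e-7",    "M",            "NO half-max for cytotoxicity inhibition"),
    c("K_Treg_supp",  "5e6",     "cells",        "Treg half-max for cytotoxicity inhibition"),
    c("K_PD1",        "1.15",    "1",            "PD-1 occupancy half-max of checkpoint Hill"),
    c("n_PD1",        "4",       "1",            "checkpoint Hill exponent"),
    # --- MDSC / cytokines -------------------------------------------------
    c("k_MDSC_rec",   "5e4",     "cells/day",    "maximal MDSC recruitment rate"),
    c("K_CCL2",       "1e-10",   "M",            "CCL2 half-max for MDSC recruitment"),
    c("MDSC_max",     "1e8",     "cells",        "MDSC carrying capacity in tumor"),
    c("k_MDSC_death", "0.05",    "1/day",        "MDSC death rate"),
    c("k_CCL2_sec",   "5e-21",   "mol/cell/day", "CCL2 secretion per cancer cell"),
    c("k_CCL2_deg",   "2",       "1/day",        "CCL2 degradation rate"),
    c("k_ArgI_sec",   "5e-18",   "mol/cell/day", "Arg-I secretion per MDSC"),
    c("k_ArgI_deg",   "5",       "1/day",        "Arg-I clearance rate"),
    c("k_NO_sec",     "1e-17",   "mol/cell/day", "NO secretion per MDSC"),
    c("k_NO_deg",     "10",      "1/day",        "NO clearance rate"),
    c("k_TGFb_sec",   "1e-19",   "mol/cell/day", "TGF-beta secretion per Treg"),
    c("k_TGFb_deg",   "5",       "1/day",        "TGF-beta clearance rate"),
    # --- PK: anti-PD-L1 (drug A) ------------------------------------------
    c("CL_A",         "0.026",   "1/day",        "anti-PD-L1 clearance from central"),
    c("k_CP_A",       "0.25",    "1/day",        "anti-PD-L1 central->peripheral"),
    c("k_PC_A",       "0.35",    "1/day",        "anti-PD-L1 peripheral->central"),
    c("k_CT_A",       "4e-6",    "1/day/cm^3",   "anti-PD-L1 central->tumor (per cm^3 tumor)"),
    c("k_TC_A",       "0.1",     "1/day",        "anti-PD-L1 tumor->central"),
    c("k_TLN_A",      "0.01",    "1/day",        "anti-PD-L1 tumor->lymph node"),
    c("k_LNC_A",      "1",       "1/day",        "anti-PD-L1 lymph node->central drainage"),
    c("MW_A",         "1.45e5",  "g/mol",        "anti-PD-L1 molecular weight"),
    # --- PK: T cell engager (drug E) --------------------------------------
    c("CL_E",         "0.35",    "1/day",        "TCE clearance from central"),
    c("k_CP_E",       "0.25",    "1/day",        "TCE central->peripheral"),
    c("k_PC_E",       "0.35",    "1/day",        "TCE peripheral->central"),
    c("k_CT_E",       "4e-6",    "1/day/cm^3",   "TCE central->tumor (per cm^3 tumor)"),
    c("k_TC_E",       "0.1",     "1/day",        "TCE tumor->central"),
    c("k_TLN_E",      "0.01",    "1/day",        "TCE tumor->lymph node"),
    c("k_LNC_E",      "1",       "1/day",        "TCE lymph node->central drainage"),
    c("MW_E",         "1.95e5",  "g/mol",        "TCE molecular weight (2+1 format)"),
    # --- binding / PD ------------------------------------------------------
    c("Kd_CD3",       "1e-7",    "M",            "TCE-CD3 arm dissociation constant"),
    c("Kd_CEA",       "3e-8",    "M",            "TCE-CEA arm dissociation constant"),
    c("chi",          "10",      "1",            "avidity factor on the second binding event"),
    c("CD3_per_T",    "1e5",     "receptors/cell", "CD3 copies per T cell"),
    c("CEA_per_C",    "3e5",     "receptors/cell", "CEA copies per cancer cell"),
    c("Kd_PD1_PDL1",  "5e-7",    "M",            "PD-1/PD-L1 dissociation constant"),
    c("Kd_A_PDL1",    "4e-10",   "M",            "anti-PD-L1/PD-L1 dissociation constant"),
    c("PD1_per_T",    "1e4",     "receptors/cell", "PD-1 copies per T cell"),
    c("PDL1_per_C",   "5e4",     "receptors/cell", "PD-L1 copies per cancer cell"),
    c("PDL1_per_Treg", "2e4",    "receptors/cell", "PD-L1 copies per Treg"),
    c("f_syn",        "1e-3",    "1",            "productive-synapse fraction of ternary complexes"),
    c("K_syn",        "30",      "synapses/cell", "synapse half-max of T cell activation"),
    c("n_syn",        "1.5",     "1",            "Hill exponent of synapse-driven activation"),
    c("beta_max",     "10.5",      "1",            "maximal TCE kill boost (multiplies kill rate)"),
    c("beta_prolif",  "0.3",       "1",            "maximal TCE boost of activated-T proliferation"),
    c("use_kill_boost",   "1",   "flag",         "gate: synapse activation boosts killing"),
    c("use_prolif_boost", "1",   "flag",         "gate: synapse activation boosts proliferation"),
    # --- inert ------------------------------------------------------------
    c("decoy",        "0.5",     "1",            "inert parameter (sensitivity-analysis control)")
  )
  # nolint end
  data.frame(name = tab[, 1], value = as.numeric(tab[, 2]),
             unit = tab[, 3], role = tab[, 4], stringsAsFactors = FALSE)
}

.qsp_par_order <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- .qsp_par_table()$name
    cache
  }
})

#' Default model parameter set
#'
#' Returns the shipped baseline parameter set: a named list of scalars with a
#' `units` attribute mapping every parameter name to its unit tag. The set
#' covers compartment geometry, tumor growth and immune killing, antigen
#' presentation, T cell trafficking/activation/exhaustion, MDSC and cytokine
#' dynamics, four-compartment antibody PK for both drugs, and the binding
#' constants of the PD-1/PD-L1 checkpoint and the CEAxCD3 engager.
#'
#' @param overrides named list or numeric vector of parameter values replacing
#'   the defaults; unknown names are an error.
#' @return object of class `qsp_params`: named list of numeric scalars with
#'   attributes `units` (named character) and `roles`.
#' @export
default_params <- function(overrides = NULL) {
  tab <- .qsp_par_table()
  p <- as.list(tab$value)
  names(p) <- tab$name
  attr(p, "units") <- stats::setNames(tab$unit, tab$name)
  attr(p, "roles") <- stats::setNames(tab$role, tab$name)
  class(p) <- "qsp_params"
  if (!is.null(overrides) && length(overrides)) {
    p <- set_params(p, overrides)
  }
  validate_params(p)
  p
}

#' Override parameters in a parameter set
#'
#' @param params a `qsp_params` object.
#' @param overrides named list/vector of replacement values.
#' @return modified `qsp_params`.
#' @export
set_params <- function(params, overrides) {
  ov <- as.list(overrides)
  if (length(ov) == 0) return(params)
  if (is.null(names(ov)) || any(!nzchar(names(ov)))) {
    stop("parameter overrides must be named")
  }
  unknown <- setdiff(names(ov), names(params))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(ov)) params[[nm]] <- as.numeric(ov[[nm]])
  validate_params(params)
  params
}

#' Validate a parameter set
#'
#' Checks non-negativity of rates, volumes and half-maxes, positivity of Hill
#' exponents and dissociation constants, and that the carrying capacity
#' exceeds the cell count of the largest screenable baseline tumor.
#'
#' @param params a `qsp_params` object.
#' @param max_d0 largest baseline diameter (cm) the cohort generator may
#'   request; the carrying capacity must exceed the corresponding cell count.
#' @return the parameter set, invisibly; errors on violation.
#' @export
validate_params <- function(params, max_d0 = 10) {
  v <- unlist(params)
  if (any(!is.finite(v))) {
    stop("non-finite parameter(s): ",
         paste(names(v)[!is.finite(v)], collapse = ", "))
  }
  if (any(v < 0)) {
    stop("negative parameter(s): ", paste(names(v)[v < 0], collapse = ", "))
  }
  pos <- c("V_C", "V_P", "V_LN", "rho_cell", "f_int", "C_max",
           "n_ratio", "n_act", "n_PD1", "n_syn",
           "Kd_CD3", "Kd_CEA", "chi", "Kd_PD1_PDL1", "Kd_A_PDL1",
           "MW_A", "MW_E", "K_ratio", "K_act", "K_PD1", "K_syn")
  bad <- pos[v[pos] <= 0]
  if (length(bad)) {
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  }
  if (params$C_max <= diameter_to_cells(max_d0, params$rho_cell)) {
    stop("C_max must exceed the cell count of the largest screenable tumor (",
         max_d0, " cm)")
  }
  ord <- .qsp_par_order()
  if (!identical(sort(names(params)), sort(ord))) {
    stop("parameter set does not match the model build")
  }
  invisible(params)
}

# Pack parameters into the numeric vector consumed by the compiled RHS;
# order is the table order, which the C header mirrors.
pack_params <- function(params) {
  as.numeric(unlist(params[.qsp_par_order()]))
}

#' Units of a parameter set
#'
#' @param params a `qsp_params` object.
#' @return named character vector of unit tags.
#' @export
param_units <- function(params) attr(params, "units")

#' @export
print.qsp_params <- function(x, ...) {
  tab <- data.frame(value = unlist(x), unit = attr(x, "units"))
  cat("QSP model parameter set (", nrow(tab), " parameters)\n", sep = "")
  print(utils::head(tab, 15))
  if (nrow(tab) > 15) cat("... and", nrow(tab) - 15, "more; see as.data.frame()\n")
  invisible(x)
}

#' @export
as.data.frame.qsp_params <- function(x, ...) {
  data.frame(name = names(x), value = unlist(x), unit = attr(x, "units"),
             role = attr(x, "roles"), row.names = NULL)
}
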