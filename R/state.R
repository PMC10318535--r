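# State vector layout. Fixed ordering; the C header mirrors it.
# Units: cells for cell pools, mol for antigen and drug amounts,
# mol/L for tumor cytokine concentrations.
.qsp_state_names <- c(
  "C",                      # cancer cells, tumor
  "P_neo", "P_self",        # free antigen pools, tumor (mol)
  "APC", "mAPC", "mAPC_LN", # antigen-presenting cells
  "nCD8_C", "nCD8_P", "nCD8_LN",
  "nCD4_C", "nCD4_P", "nCD4_LN",
  "aCD8_LN", "aCD4_LN",     # activated T cells in the lymph node
  "Teff_C", "Teff_T",
  "Th_C", "Th_T",
  "Treg_C", "Treg_T",
  "Texh_T",
  "MDSC_T",
  "CCL2", "ArgI", "NO", "TGFb",   # tumor cytokines (M)
  "A_C", "A_P", "A_T", "A_LN",    # anti-PD-L1 amounts (mol)
  "E_C", "E_P", "E_T", "E_LN"     # T cell engager amounts (mol)
)

#' State vector species names
#'
#' @return character vector giving the fixed ordering of the model state.
#' @export
state_names <- function() .qsp_state_names

#' Initial model state at tumor seeding
#'
#' Builds the pre-treatment initial condition: a small seeded cancer cell
#' population, naive T cell pools at their drug-free steady state, the
#' resting APC pool, and every other species at zero.
#'
#' @param params a `qsp_params` parameter set.
#' @return named numeric vector of class `qsp_state`.
#' @export
initial_state <- function(params) {
  s <- stats::setNames(numeric(length(.qsp_state_names)), .qsp_state_names)
  s["C"] <- params$C_seed
  s["APC"] <- params$APC_base
  # drug-free steady state of the naive trafficking subsystem
  # (source into central; death everywhere; C<->P and C<->LN exchange)
  ss <- .naive_steady_state(params)
  for (lin in c("nCD8", "nCD4")) {
    s[paste0(lin, "_C")] <- ss["central"]
    s[paste0(lin, "_P")] <- ss["peripheral"]
    s[paste0(lin, "_LN")] <- ss["ln"]
  }
  class(s) <- c("qsp_state", class(s))
  s
}

# Linear steady state of one naive lineage (3x3 solve)
.naive_steady_state <- function(params) {
  kd <- params$k_nT_death
  A <- matrix(c(
    -(kd + params$k_CP + params$k_CLN), params$k_PC,              params$k_LNC,
    params$k_CP,                        -(kd + params$k_PC),      0,
    params$k_CLN,                       0,                        -(kd + params$k_LNC)
  ), nrow = 3, byrow = TRUE)
  b <- c(-params$k_nT_source, 0, 0)
  x <- solve(A, b)
  stats::setNames(pmax(x, 0), c("central", "peripheral", "ln"))
}

.state_index <- function(name) match(name, .qsp_state_names)
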