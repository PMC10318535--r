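---
title: "Model and methods: tumor-immune dynamics, virtual trials, and synergy"
author: "qspio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: tumor-immune dynamics, virtual trials, and synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(qspio)
```

## Scope

`qspio` is a quantitative systems pharmacology (QSP) platform for
immuno-oncology in colorectal cancer. It couples a reduced mechanistic
tumor-immune ODE model to the pharmacokinetics and pharmacodynamics of two
antibody therapeutics — an anti-PD-L1 checkpoint inhibitor dosed like
atezolizumab (1200 mg every three weeks) and a CEAxCD3 bispecific T cell
engager dosed like cibisatamab (tens of mg weekly) — and wraps that model
in virtual-clinical-trial machinery: Latin hypercube virtual patients with
plausibility screening, RECIST 1.1 response scoring, bootstrap confidence
intervals for overall response rates (ORR), partial-rank-correlation
sensitivity analysis, dose/schedule grids, and MuSyC synergy-surface
fitting.

## The reduced model

The model tracks ~34 species across four compartments: central (blood),
peripheral, tumor, and tumor-draining lymph node. One species stands for
each mechanistic role rather than reproducing a full supplementary species
listing; every mechanism is named below.

**Tumor.** Cancer cells grow logistically (`k_growth`, carrying capacity
`C_max`) and die by first-order apoptosis (`k_apop`) and by T-cell killing.
The kill rate is

    k_kill * C * hill(Teff_T / C, K_ratio, n_ratio)
      * (1 + beta_max * a_syn) * (1 - inh_PD1) * (1 - suppression)

i.e. killing depends on the effector-to-target ratio through a saturating
Hill term, is boosted by engager-formed cytolytic synapses, and is
attenuated by checkpoint signaling and by a suppression fraction that
combines arginase-I, nitric oxide and regulatory T cell (Treg) terms as
independent multiplicative `(1 - hill)` factors. Each inhibition is stated
mechanistically in the source material but not their composition; treating
them as independent inhibitions is the package's design choice.

**Antigen and APCs.** Dying cancer cells release neo- and self-antigen
pools that are taken up by antigen-presenting cells in the tumor. The
peptide-cleavage / MHC-loading / surface-transport sub-steps are lumped
into a single saturating "antigen drive": APC maturation is a Hill
function of the free antigen pool, and downstream naive T cell activation
is a Hill function (`K_act`, `n_act`) of the mature-APC count in the lymph
node, scaled for CD8 cells by the neoantigen-specific T cell clone number
`TCC`.

**T cell life cycle.** Naive CD4/CD8 cells are sourced into the central
compartment, traffic between central, peripheral and lymph node
compartments, and are activated in the lymph node. Activated cells
proliferate (logistically capped), egress to the central compartment —
CD8 cells as effectors, CD4 cells split into helper (Th) and regulatory
(Treg) lineages by a fixed fraction `f_Treg` — and infiltrate the tumor at
a rate proportional to the central pool and a saturating function of tumor
burden. In the tumor, effectors are lost to death and to exhaustion with
two drives: ligand-bound PD-1 (through the same checkpoint Hill as
killing) and Tregs. TGF-beta and arginase-I drive Th-to-Treg
trans-differentiation; CCL2 secreted by cancer cells recruits
myeloid-derived suppressor cells (MDSCs), which release arginase-I and
nitric oxide.

**Pharmacokinetics.** Both antibodies follow linear four-compartment PK:
clearance from central, bidirectional central-peripheral and central-tumor
exchange (tumor influx scaled by current tumor volume), unidirectional
tumor-to-lymph-node lymphatic transport, and lymph-node drainage back to
central, which closes the mass balance. Doses are instantaneous
intravenous boluses (mg converted to moles by molecular weight). Default
PK constants give a terminal half-life near four weeks for the checkpoint
antibody and around two days for the engager. Molecular weights
(1.45e5 and 1.95e5 g/mol) are configuration defaults.

**Checkpoint pharmacodynamics.** PD-1 occupancy is a competitive binding
equilibrium on the PD-L1 axis: the drug sequesters PD-L1; remaining free
PD-L1 binds PD-1. PD-1 and PD-L1 totals are conserved; the antibody is
treated as buffered at its free interstitial concentration because the
tumor drug pool exchanges continuously with the much larger systemic
reservoir — with strict drug conservation inside the solve, a
receptor-rich tumor would deplete its local antibody pool and the
equilibrium would understate target engagement between doses. Under
buffering the equilibrium reduces to a quadratic in free PD-L1. The
occupancy fraction feeds a Hill (`K_PD1`, `n_PD1`) that both attenuates
killing and drives exhaustion.

**Engager pharmacodynamics.** The bispecific binds CD3 on T cells and CEA
on cancer cells. Following the one-arm simplification with an avidity
factor, each binary complex plus the second target forms the ternary
synapse with the second event's affinity multiplied by `chi`. The
quasi-steady-state ternary complex is solved algebraically inside the ODE
right-hand side (binding equilibrates fast relative to cell dynamics): at
fixed free engager the network reduces to a quadratic, and the free
engager concentration is a monotone scalar root. All three totals are
conserved, and the solution exhibits the characteristic bell-shaped (hook)
dose dependence. Synapses per T cell feed an activation Hill (`K_syn`,
`n_syn`) calibrated against synthetic activation-vs-synapse data (the
underlying in vitro values are not public; `fit_activation_hill` is
validated by parameter recovery instead). Activation boosts killing
(`beta_max`) and, gated by configuration, activated-T proliferation
(`beta_prolif`); both gates default to on.

## Numerical choices

The right-hand side exists twice by design: a reference R implementation
(`assemble_rhs`) that defines the model, and a compiled C copy integrated
by `deSolve::lsoda` for speed; the test suite asserts elementwise
agreement on randomized states. Dose events restart the integrator with a
bolus added to the central drug amount. Relative tolerance is 1e-6 with
per-species absolute tolerances scaled to typical magnitudes (cell counts
versus molar amounts span ~25 orders of magnitude). Solver output is
verified non-negative to a relative tolerance of 1e-8 and clipped to zero;
worse violations raise an error naming the species. Baseline tumors are
grown from a small seed with a root-stopping integrator that halts exactly
at the target diameter.

The binding solves use closed-form quadratics plus a bracketed scalar root
(bisection in C, `uniroot` in R), making the pharmacodynamic layer cheap
enough to evaluate inside every RHS call.

## Virtual patients and calibration

Nine physiological parameters and one deliberately inert `decoy` are
varied across patients (baseline diameter, growth rate, clone number, kill
rate, CEA and PD-L1 densities, naive T source, Treg-driven exhaustion,
MDSC recruitment), sampled by Latin hypercube, most on a log scale.
Candidates are screened on three observables: the tumor must actually
reach its sampled baseline diameter within 5000 days (slow growers and
strongly immune-controlled tumors are "non-patients"), blood T cell
density must fall in 3e5-5e6 cells/mL, and the baseline tumor Teff:Treg
ratio in 0.1-50. The screens are named in the source material; the
windows are package choices set to physiological ranges.

Baseline values and sampling ranges are configuration-level choices, not
transcriptions: they were set so that the model's virtual cohort
reproduces the published clinical response rates after the prescribed
range calibration. `calibrate_ranges` implements that calibration as a
greedy coordinate search over the bounds of the "calibrated"-tagged ranges
(clone number, kill rate, Treg exhaustion), multiplying one bound at a
time by factors {1.25, 2, 0.8, 0.5} — the kill rate first, upper bounds
first, because the upper tail of the kill distribution is what moves small
response rates — and accepting when every arm's simulated ORR falls inside
its clinical confidence band.

The cohort emulates inter-patient variability as independent draws of
mechanistic parameters. It does not emulate measurement noise on tumor
diameters, lesion multiplicity, dropout, immunogenicity, or correlated
parameter structure; passing tests therefore demonstrate internal
consistency of the pipeline and reproduction of cohort-level response
statistics, not patient-level predictive validity.

## Trials, response scoring, and analyses

Treatment simulations start at the day the tumor reaches baseline (t = 0).
RECIST 1.1 is applied to the single lesion diameter at assessments every
8 weeks: partial response at >= 30% shrinkage from baseline, progression
at >= 20% growth over the nadir plus 0.5 cm absolute, complete response
below 0.2 cm, best overall response without a confirmation scan (the
source cites RECIST 1.1 without restating thresholds; these are the
standard ones). ORR confidence intervals are percentile bootstrap —
resampling 31 patients (monotherapies) or 25 (combination) 10,000 times —
matching the cited clinical trial sizes; the BCa variant is deliberately
not used.

PRCC rank-transforms the sampled parameters and outcome and correlates
residuals after regressing out all other parameters' ranks; p-values use
the partial-correlation t transform with N - P - 2 degrees of freedom and
no multiplicity correction. The inert `decoy` parameter provides a
negative control whose PRCC should fall within +/- 2/sqrt(N).

The synergy surface is the 5x5 grid of median tumor-size ratios (treated
over untreated volume at day 400; diameter available by flag) over
engager doses 0-80 mg and checkpoint doses 0-1600 mg. The MuSyC fit uses
the two-parameter formulation without cooperativity synergy: single-drug
Hill edges (E0, E1, h1, C1) and (E0, E2, h2, C2); each drug's potency
rescaled by the other's alpha; and the combination plateau
E3 = min(E1, E2) - beta * (E0 - min(E1, E2)), so beta measures the gain
of the combination's maximal effect over the best single agent and beta =
0 is the additive null in efficacy. Both alphas are estimated; alpha_2 is
the reported one. Fitting is Levenberg-Marquardt with seeded multistart on
log-transformed positive parameters. Because the surface uses the
median-patient response while ORR is a tail statistic, a near-additive
surface (small |beta|, small |log alpha|) is compatible with arms whose
ORRs are not exactly additive.

## Problem sizes

The shipped analyses use a 500-draw cohort (roughly 45% are accepted
after screening; most rejections are strong-immunity draws whose tumors
never reach their sampled baseline diameter), 400-day horizons, 10,000
bootstrap replicates, and the full accepted cohort for the 25-cell
synergy surface. A subsampled surface was considered and rejected: with
median effects of a few percent, medians over small subsamples give the
synergy fit heavy tails, while the full-cohort surface keeps the fitted
beta stable to roughly +/-0.05 across cohort seeds. The complete
calibration-plus-three-arms-plus-surface pipeline runs in about four
minutes on one core, with response rates stable to about two percentage
points across seeds.

## Known limitations

Single lesion per patient; no resistance evolution, spatial structure, or
cytokine-release toxicity; cytokine concentrations ignore dilution by
tumor volume change; exhausted T cells retain no killing capacity; antigen
"neo" versus "self" pools drive a single effective T cell clone pool
scaled by `TCC` rather than clone-resolved repertoires; checkpoint
occupancy treats the antibody as buffered (see above). The dose grids
treat regimens as fixed-interval boluses; infusion kinetics and
target-mediated disposition are out of scope.
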