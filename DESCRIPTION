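Package: qspio
Title: Quantitative Systems Pharmacology Virtual Trials for Checkpoint
    Inhibitor and T Cell Engager Combination Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular quantitative systems pharmacology (QSP) platform for
    immuno-oncology built around a reduced four-compartment tumor-immune
    ordinary differential equation model of colorectal cancer. Couples
    logistic tumor growth, T cell activation and trafficking, checkpoint
    (PD-1/PD-L1) inhibition, myeloid-derived suppressor cell recruitment and
    regulatory T cell suppression to the pharmacokinetics and
    pharmacodynamics of an anti-PD-L1 antibody and a CEAxCD3 bispecific
    T cell engager. Provides Latin hypercube virtual-patient generation with
    physiological plausibility screening, RECIST 1.1 response scoring,
    bootstrap confidence intervals for overall response rates, partial rank
    correlation sensitivity analysis, dose/schedule grid optimization and
    MuSyC drug-synergy surface fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
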