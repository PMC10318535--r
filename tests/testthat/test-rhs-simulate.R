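# Model right-hand side and solver driver.

test_that("compiled and reference right-hand sides agree", {
  p <- default_params()
  pv <- qspio:::pack_params(p)
  set.seed(3)
  for (i in 1:25) {
    s <- initial_state(p)
    s["C"] <- 10^stats::runif(1, 6, 11)
    s["P_neo"] <- 10^stats::runif(1, -14, -10)
    s["P_self"] <- 10^stats::runif(1, -14, -10)
    s[c("APC", "mAPC", "mAPC_LN")] <- 10^stats::runif(3, 2, 5)
    s[c("aCD8_LN", "aCD4_LN")] <- 10^stats::runif(2, 5, 8)
    s[c("Teff_C", "Th_C", "Treg_C")] <- 10^stats::runif(3, 6, 9)
    s[c("Teff_T", "Th_T", "Treg_T", "Texh_T")] <- 10^stats::runif(4, 4, 8)
    s["MDSC_T"] <- 10^stats::runif(1, 4, 7)
    s[c("CCL2", "ArgI", "NO", "TGFb")] <- 10^stats::runif(4, -12, -8)
    s[c("A_C", "A_P", "A_T", "A_LN")] <- 10^stats::runif(4, -10, -6)
    s[c("E_C", "E_P", "E_T", "E_LN")] <- 10^stats::runif(4, -12, -8)
    dR <- assemble_rhs(0, s, p)
    dC <- deSolve::DLLfunc(func = "qsp_deriv", dllname = "qspio",
                           initfunc = "qsp_init", times = 0,
                           y = as.numeric(s), parms = pv)$dy
    expect_equal(unname(dR), unname(dC), tolerance = 1e-6)
  }
})

test_that("derivatives are finite and shaped like the state", {
  p <- default_params()
  s <- initial_state(p)
  d <- assemble_rhs(0, s, p)
  expect_length(d, length(state_names()))
  expect_true(all(is.finite(d)))
  expect_identical(names(d), state_names())
})

test_that("isolated tumor follows the logistic-with-death closed form", {
  # immune system disabled: no naive source, no resting APCs
  p <- default_params(overrides = list(k_nT_source = 0, APC_base = 0))
  init <- initial_state(p)
  expect_true(all(init[grep("nCD", state_names())] == 0))
  tr <- simulate_model(p, list(), init = init, t_end = 400)
  r <- p$k_growth; a <- p$k_apop; K <- p$C_max
  r_eff <- r - a; K_eff <- K * r_eff / r
  C0 <- p$C_seed
  C_exact <- K_eff / (1 + (K_eff / C0 - 1) * exp(-r_eff * tr$time))
  expect_equal(tr$states[, "C"], C_exact, tolerance = 1e-4,
               ignore_attr = TRUE)
  # cancer-only state: RHS tumor term equals the hand-coded logistic
  s <- init; s["C"] <- 1e9
  d <- assemble_rhs(0, s, p)
  expect_equal(d[["C"]], r * 1e9 * (1 - 1e9 / K) - a * 1e9, tolerance = 1e-12)
})

test_that("drug channels stay identically zero without treatment", {
  p <- default_params()
  tr <- simulate_model(p, list(), init = initial_state(p), t_end = 100)
  drug_cols <- c("A_C", "A_P", "A_T", "A_LN", "E_C", "E_P", "E_T", "E_LN")
  expect_true(all(tr$states[, drug_cols] == 0))
})

test_that("simulation is deterministic and states stay non-negative", {
  p <- default_params()
  regs <- list(regimen("tce", 60, 7, 0), regimen("apdl1", 1200, 21, 0))
  tr1 <- simulate_model(p, regs, init = initial_state(p), t_end = 150)
  tr2 <- simulate_model(p, regs, init = initial_state(p), t_end = 150)
  expect_identical(tr1$states, tr2$states)
  expect_true(all(tr1$states >= 0))
})

test_that("random virtual-patient parameterizations integrate cleanly", {
  # non-negativity guard: the driver errors if any species dips below
  # tolerance, so a clean run is the assertion
  draws <- lhs_sample(default_ranges(), 12, seed = 9)
  for (i in seq_len(nrow(draws))) {
    ov <- as.list(draws[i, ])
    p <- set_params(default_params(), ov[names(ov) %in%
                                           names(default_params())])
    tr <- simulate_model(p, list(regimen("tce", 60, 7, 0)),
                         init = initial_state(p), t_end = 400)
    expect_true(all(tr$states >= 0))
  }
})

test_that("trajectory derived channels recompute from states", {
  p <- default_params()
  tr <- simulate_model(p, list(), init = initial_state(p), t_end = 50)
  expect_true(all(diff(tr$time) > 0))
  g <- tumor_volume_and_diameter(tr$states[, "C"], p$rho_cell)
  expect_equal(tr$volume_cm3, g$volume_cm3)
  expect_equal(tr$diameter_cm, g$diameter_cm)
  df <- as.data.frame(tr)
  expect_true(all(c("time", "tumor_volume_cm3", "tumor_diameter_cm") %in%
                    names(df)))
})

test_that("grow_to_baseline lands on the target diameter or reports status", {
  p <- default_params()
  g <- grow_to_baseline(p, 2)
  expect_equal(g$status, "ok")
  expect_equal(g$diameter_cm, 2, tolerance = 0.01)
  # pre-treatment growth is monotone under default parameters
  tr <- simulate_model(p, list(), init = initial_state(p),
                       t_end = ceiling(g$t_reach))
  expect_true(all(diff(tr$diameter_cm) > -1e-9))
  # unreachable: target above carrying capacity
  g2 <- grow_to_baseline(p, 15)
  expect_equal(g2$status, "non-patient: unreachable")
  # growth shut off: target never reached within the horizon cap
  p0 <- set_params(p, list(k_growth = 0))
  g3 <- grow_to_baseline(p0, 2, horizon_cap = 300)
  expect_match(g3$status, "unreachable")
})
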