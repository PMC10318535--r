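# Pharmacodynamic binding algebra: ternary-complex QSS with avidity,
# checkpoint occupancy, and the activation Hill fit.

bp0 <- binding_params(default_params())

test_that("ternary QSS matches the long-time limit of the mass-action ODE", {
  # independent oracle: integrate the six-species binding network to
  # equilibrium and compare the ternary complex concentration
  for (chi in c(1, 10)) {
    bp <- bp0; bp$chi <- chi
    E0 <- 2e-9; CD3 <- 8e-10; CEA <- 5e-9
    kon <- 1e8  # 1/M/day, arbitrary: equilibrium is kon-independent
    rhs <- function(t, y, p) {
      e <- y[1]; c3 <- y[2]; cea <- y[3]; b3 <- y[4]; bC <- y[5]; TT <- y[6]
      v1 <- kon * e * c3 - kon * bp$Kd_CD3 * b3          # E + CD3 <-> E.CD3
      v2 <- kon * e * cea - kon * bp$Kd_CEA * bC         # E + CEA <-> E.CEA
      v3 <- kon * b3 * cea - kon * (bp$Kd_CEA / chi) * TT  # E.CD3 + CEA <-> T
      v4 <- kon * bC * c3 - kon * (bp$Kd_CD3 / chi) * TT   # E.CEA + CD3 <-> T
      list(c(-v1 - v2, -v1 - v4, -v2 - v3, v1 - v3, v2 - v4, v3 + v4))
    }
    eq <- deSolve::ode(c(E0, CD3, CEA, 0, 0, 0), c(0, 1e4), rhs, NULL,
                       rtol = 1e-10, atol = 1e-22)
    tern_ode <- unname(eq[2, 7])
    qss <- ternary_complex_qss(E0, CD3, CEA, bp)
    expect_equal(qss$ternary, tern_ode, tolerance = 1e-4)
    # all three conservation laws hold
    expect_equal(qss$e + qss$b3 + qss$bC + qss$ternary, E0,
                 tolerance = 1e-8)
    expect_equal(qss$c3 + qss$b3 + qss$ternary, CD3, tolerance = 1e-8)
    expect_equal(qss$cea + qss$bC + qss$ternary, CEA, tolerance = 1e-8)
  }
})

test_that("engager dose response is bell-shaped (hook effect)", {
  p <- default_params()
  bp <- binding_params(p)
  # receptor concentrations of a typical 3 cm tumor with infiltrate
  V_int <- (diameter_to_cells(3, p$rho_cell) / p$rho_cell / 1000) * p$f_int
  CEA <- p$CEA_per_C * diameter_to_cells(3, p$rho_cell) /
    (6.02214076e23 * V_int)
  CD3 <- p$CD3_per_T * 1e7 / (6.02214076e23 * V_int)
  E_grid <- 10^seq(-12, -5, length.out = 60)
  syn <- vapply(E_grid, synapse_per_tcell, numeric(1),
                CEA_tot = CEA, CD3_tot = CD3, bp = bp)
  i_max <- which.max(syn)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(E_grid))
  expect_lt(syn[length(E_grid)], max(syn))   # falls past the peak
  expect_equal(synapse_per_tcell(0, CEA, CD3, bp), 0)
})

test_that("synapse count is non-decreasing in the avidity factor", {
  E0 <- 5e-9; CD3 <- 8e-10; CEA <- 5e-9
  syn <- vapply(c(0.5, 1, 2, 5, 10, 50), function(chi) {
    bp <- bp0; bp$chi <- chi
    synapse_per_tcell(E0, CEA, CD3, bp)
  }, numeric(1))
  expect_true(all(diff(syn) >= -1e-12))
})

test_that("PD-1 occupancy matches the drug-free quadratic and saturates", {
  bp <- bp0
  P <- 8e-11; L <- 1.5e-7
  # drug-free closed form: free PD-L1 from the two-species quadratic
  a <- 1; b <- bp$Kd_PD1_PDL1 + P - L; cc <- -L * bp$Kd_PD1_PDL1
  Lfree <- (-b + sqrt(b^2 - 4 * a * cc)) / 2
  H_expected <- (Lfree / bp$Kd_PD1_PDL1) / (1 + Lfree / bp$Kd_PD1_PDL1)
  expect_equal(pd1_occupancy(0, P, L, bp), H_expected, tolerance = 1e-10)
  # saturating drug abolishes occupancy
  expect_lt(pd1_occupancy(1e6 * bp$Kd_A_PDL1, P, L, bp), 1e-3)
  # receptor conservation at the solution: recompute bound species
  A <- 3e-8
  H <- pd1_occupancy(A, P, L, bp)
  Lf <- bp$Kd_PD1_PDL1 * H / (1 - H)
  bound_pd1 <- P * H
  bound_drug <- L - Lf - bound_pd1
  expect_equal(Lf + bound_drug + bound_pd1, L, tolerance = 1e-8)
})

test_that("PD-1 occupancy is in [0,1] and strictly decreasing in drug", {
  set.seed(11)
  for (i in 1:200) {
    H <- pd1_occupancy(10^stats::runif(1, -12, -5),
                       10^stats::runif(1, -12, -6),
                       10^stats::runif(1, -12, -6), bp0)
    expect_true(H >= 0 && H <= 1)
  }
  A_grid <- 10^seq(-11, -6, length.out = 30)
  H <- vapply(A_grid, pd1_occupancy, numeric(1),
              PD1_tot = 8e-11, PDL1_tot = 1.5e-7, bp = bp0)
  expect_true(all(diff(H) < 0))
})

test_that("activation Hill fit recovers generating parameters", {
  # noiseless self-consistency at machine-level tolerance
  d <- gen_activation_data(K_true = 5, n_true = 2, n_points = 12, noise = 0)
  fit <- fit_activation_hill(d)
  expect_true(fit$converged)
  expect_equal(fit$K_syn, 5, tolerance = 1e-6)
  expect_equal(fit$n_syn, 2, tolerance = 1e-6)
  # 5% multiplicative noise: median estimate within 10% over replicates
  n_hat <- vapply(1:60, function(s) {
    fit_activation_hill(gen_activation_data(5, 2, 12, noise = 0.05,
                                            seed = s))$n_syn
  }, numeric(1))
  expect_lt(abs(stats::median(n_hat) - 2) / 2, 0.10)
})

test_that("degenerate activation data is rejected as unidentifiable", {
  flat <- data.frame(synapses = c(1, 2, 4, 8), activation = rep(0.5, 4))
  expect_error(fit_activation_hill(flat), "unidentifiable")
  expect_error(fit_activation_hill(data.frame(synapses = 1:3,
                                              activation = c(.1, .2, .3))),
               "at least 4")
  bad <- data.frame(synapses = c(1, 2, 4, 8), activation = c(0.1, 0.5, 2, 1))
  expect_error(fit_activation_hill(bad), "\\[0, 1\\]")
})
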