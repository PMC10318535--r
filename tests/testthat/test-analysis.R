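# PRCC sensitivity analysis and MuSyC synergy fitting.

test_that("PRCC separates a driving parameter from noise", {
  set.seed(21)
  N <- 200
  X <- cbind(x1 = stats::runif(N), x2 = stats::runif(N))
  y <- X[, "x1"]
  r <- prcc(X, y)
  expect_gt(r$prcc[r$name == "x1"], 0.99)
  expect_lt(abs(r$prcc[r$name == "x2"]), 0.2)
  expect_lt(r$p_value[r$name == "x1"], 1e-10)
  expect_true(all(abs(r$prcc) <= 1))
  # rank invariance: monotone transform of the outcome changes nothing
  r2 <- prcc(X, exp(y))
  expect_equal(r$prcc, r2$prcc, tolerance = 1e-12)
})

test_that("PRCC rejects degenerate inputs", {
  X <- cbind(a = 1:20, b = rep(2, 20))
  expect_error(prcc(X, rnorm(20)), "constant column")
  expect_error(prcc(cbind(a = 1:5), rnorm(4)), "length")
  expect_error(prcc(matrix(runif(12), 4, 3), runif(4)), "N > P \\+ 2")
})

musyc_truth <- list(E0 = 1, E1 = 0.25, E2 = 0.85, h1 = 1.4, h2 = 1.1,
                    C1 = 25, C2 = 520, alpha1 = exp(0.5), alpha2 = exp(0.5),
                    beta = 0.2)

test_that("MuSyC fit recovers generating parameters from a clean surface", {
  surf <- gen_musyc_surface(musyc_truth,
                            tce_doses = c(0, 10, 25, 50, 100),
                            apdl1_doses = c(0, 130, 400, 1200, 3000))
  fit <- fit_musyc(surf, seed = 2)
  expect_true(fit$converged)
  expect_equal(fit$beta, 0.2, tolerance = 0.05)
  expect_equal(fit$log_alpha2, 0.5, tolerance = 0.05 * 0.5 + 0.05)
  expect_equal(fit$E1, musyc_truth$E1, tolerance = 0.05)
  expect_equal(fit$C1, musyc_truth$C1, tolerance = 0.05 * 25)
})

test_that("a Bliss-independent surface fits as near-additive", {
  # independent action of a strong and a weak agent: survival multiplies
  d1 <- c(0, 10, 25, 50, 100); d2 <- c(0, 130, 400, 1200, 3000)
  S1 <- 1 - 0.7 * hill(d1, 25, 1.4)     # strong edge, E1 = 0.3
  S2 <- 1 - 0.03 * hill(d2, 520, 1.1)   # weak edge, E2 = 0.97
  E <- outer(S1, S2)
  surf <- structure(list(tce_doses = d1, apdl1_doses = d2, E = E,
                         metric = "synthetic"), class = "dose_surface")
  fit <- fit_musyc(surf, seed = 3)
  expect_lt(abs(fit$beta), 0.02)
  expect_lt(abs(fit$log_alpha2), 0.05)
})

test_that("synergy parameters are invariant to rescaling the dose axes", {
  surf <- gen_musyc_surface(musyc_truth)
  fit <- fit_musyc(surf, seed = 2)
  surf2 <- surf
  surf2$tce_doses <- surf$tce_doses * 10
  surf2$apdl1_doses <- surf$apdl1_doses * 0.5
  fit2 <- fit_musyc(surf2, seed = 2)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-3)
  expect_equal(fit2$log_alpha2, fit$log_alpha2, tolerance = 1e-3)
  expect_equal(fit2$C1, fit$C1 * 10, tolerance = 0.01 * fit$C1 * 10)
  expect_equal(fit2$C2, fit$C2 * 0.5, tolerance = 0.01 * fit$C2)
})

test_that("fit_musyc validates its input surface", {
  surf <- gen_musyc_surface(musyc_truth, tce_doses = c(0, 10, 40),
                            apdl1_doses = c(0, 100, 400))
  expect_error(fit_musyc(surf), "4x4")
  surf2 <- gen_musyc_surface(musyc_truth, tce_doses = c(5, 10, 20, 40),
                             apdl1_doses = c(0, 100, 200, 400))
  expect_error(fit_musyc(surf2), "edges")
})
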