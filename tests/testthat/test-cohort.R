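# Virtual cohort generation: LHS stratification, screening, reproducibility.

test_that("LHS samples are stratified per parameter", {
  rng <- data.frame(name = "p", lower = 0, upper = 1, scale = "linear",
                    provenance = "literature")
  s <- sort(lhs_sample(rng, 10, seed = 1)$p)
  expect_true(all(s >= (0:9) / 10 & s < (1:10) / 10))
  # log-scaled parameter stratifies in log space
  rngl <- data.frame(name = "q", lower = 1e-3, upper = 1e-1, scale = "log",
                     provenance = "literature")
  q <- lhs_sample(rngl, 20, seed = 2)$q
  bins <- cut(log10(q), breaks = seq(-3, -1, length.out = 21))
  expect_true(all(table(bins) == 1))
  # seeded reproducibility
  expect_identical(lhs_sample(default_ranges(), 25, seed = 7),
                   lhs_sample(default_ranges(), 25, seed = 7))
  bad <- default_ranges(); bad$lower[1] <- bad$upper[1]
  expect_error(lhs_sample(bad, 5, seed = 1), "invalid ranges")
})

test_that("screening statuses are sound and idempotent", {
  # zero growth rate cannot reach any baseline diameter
  vp0 <- screen_patient(list(k_growth = 0, d_0 = 3))
  expect_equal(vp0$status, "non-patient: unreachable")
  expect_null(vp0$state)
  # default parameters are an accepted patient
  vp <- screen_patient(list())
  expect_equal(vp$status, "accepted")
  expect_false(is.null(vp$state))
  expect_equal(vp$baseline_diameter, default_params()$d_0, tolerance = 0.011)
  # rerunning the screen on an accepted patient accepts it again
  vp2 <- screen_patient(vp$overrides)
  expect_equal(vp2$status, "accepted")
  expect_equal(vp2$state, vp$state)
})

test_that("relaxing a screening window never rejects more patients", {
  draws <- lhs_sample(default_ranges(), 8, seed = 31)
  tight <- default_screens()
  loose <- tight; loose$teff_treg <- c(0, Inf)
  st_tight <- vapply(seq_len(nrow(draws)), function(i)
    screen_patient(as.list(draws[i, ]), screens = tight)$status, "")
  st_loose <- vapply(seq_len(nrow(draws)), function(i)
    screen_patient(as.list(draws[i, ]), screens = loose)$status, "")
  expect_gte(sum(st_loose == "accepted"), sum(st_tight == "accepted"))
})

test_that("cohorts partition draws and reproduce under a fixed seed", {
  coh <- small_cohort()
  expect_equal(length(coh$patients) + length(coh$rejected), coh$N)
  coh2 <- generate_cohort(N = coh$N, seed = coh$seed)
  expect_identical(lapply(coh2$patients, `[[`, "overrides"),
                   lapply(coh$patients, `[[`, "overrides"))
  # every accepted patient passes all screens on re-check
  for (vp in coh$patients) {
    expect_true(vp$blood_T >= coh$screens$blood_T[1] &&
                  vp$blood_T <= coh$screens$blood_T[2])
    expect_true(vp$teff_treg >= coh$screens$teff_treg[1] &&
                  vp$teff_treg <= coh$screens$teff_treg[2])
  }
  sub <- subsample_cohort(coh, 3, seed = 2)
  expect_length(sub$patients, 3)
})

test_that("calibration is a no-op when targets are already satisfied", {
  coh <- small_cohort()
  # loose targets that the default configuration satisfies trivially
  targets <- list(list(regimens = list(regimen("tce", 60, 7, 0)),
                       orr = 6, ci = c(0, 100)))
  cal <- calibrate_ranges(default_ranges(), targets, budget = 3,
                          N = coh$N, seed = coh$seed)
  expect_true(cal$success)
  expect_equal(cal$evaluations, 1)
  expect_identical(cal$ranges, default_ranges())
  expect_error(calibrate_ranges(default_ranges(), list()), "nonempty")
})
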