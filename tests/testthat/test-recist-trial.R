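# RECIST 1.1 classification, bootstrap CIs and the trial engine.

test_that("RECIST categories follow the threshold rules", {
  s <- diam_series(-0.35)             # monotone shrink to -35%
  expect_equal(classify_response(s$time, s$diameter)$best_response, "PR")
  s <- diam_series(0)                 # flat
  expect_equal(classify_response(s$time, s$diameter)$best_response, "SD")
  # growth +25% from nadir with +0.6 cm absolute (baseline 2.4 cm),
  # established before the first assessment so every scan reads PD
  t <- 0:400; d <- ifelse(t < 14, 2.4, 3.0)
  expect_equal(classify_response(t, d)$best_response, "PD")
  # shrink below the CR threshold
  t <- 0:400; d <- pmax(5 * exp(-0.03 * t), 0.01)
  expect_equal(classify_response(t, d)$best_response, "CR")
  # small absolute growth of a small lesion is SD, not PD (0.5 cm rule)
  s <- diam_series(0.25, baseline = 1)
  expect_equal(classify_response(s$time, s$diameter)$best_response, "SD")
  expect_error(classify_response(numeric(0), numeric(0)), "empty")
})

test_that("best overall response uses the best assessment, nadir updates", {
  # shrink to -40% by day 200 then regrow past baseline: best is PR
  t <- 0:400
  d <- ifelse(t <= 200, 5 * (1 - 0.002 * t), 3 + 0.02 * (t - 200))
  rec <- classify_response(t, d)
  expect_equal(rec$best_response, "PR")
  expect_equal(rec$best_change_pct, -40, tolerance = 0.5)
  expect_equal(rec$nadir_cm, 3, tolerance = 0.01)
  # late assessments against the nadir are PD
  cats <- rec$assessments$category
  expect_equal(cats[length(cats)], "PD")
})

test_that("bootstrap ORR CI matches the closed-form binomial oracle", {
  # responder indicator vector with true ORR 8% (resampling a record set
  # of known composition is Binomial(k, p-hat))
  resp <- rep(c(TRUE, FALSE), c(8, 92))
  ci <- bootstrap_orr_ci(resp, k = 31, reps = 10000, seed = 4)
  oracle <- 100 * stats::qbinom(c(0.025, 0.975), 31, 0.08) / 31
  expect_lt(abs(ci[["lower"]] - oracle[1]), 1)
  expect_lt(abs(ci[["upper"]] - oracle[2]), 1)
  expect_true(ci[["lower"]] <= ci[["median"]] &&
                ci[["median"]] <= ci[["upper"]])
  # degenerate record sets pin the interval
  all_cr <- rep(TRUE, 20)
  expect_equal(unname(bootstrap_orr_ci(all_cr, 31, 1000, 1)),
               c(100, 100, 100))
  none <- rep(FALSE, 20)
  expect_equal(unname(bootstrap_orr_ci(none, 31, 1000, 1)), c(0, 0, 0))
  expect_error(bootstrap_orr_ci(logical(0), 31), "empty")
})

test_that("trial engine scores a cohort and is deterministic", {
  coh <- small_cohort()
  expect_gt(length(coh$patients), 2)
  # untreated arm: tumors only grow, ORR is exactly 0
  t0 <- run_trial(coh, list(), horizon = 400, bootstrap = FALSE)
  expect_equal(t0$orr, 0)
  expect_equal(t0$n, length(coh$patients))
  # identical inputs give identical results
  regs <- list(regimen("tce", 60, 7, 0))
  t1a <- run_trial(coh, regs, bootstrap = FALSE)
  t1b <- run_trial(coh, regs, bootstrap = FALSE)
  expect_identical(t1a$diameters, t1b$diameters)
  # ORR arithmetic on a synthetic record set: 3 responders of 25
  resp <- rep(c(TRUE, FALSE), c(3, 22))
  expect_equal(100 * mean(resp), 12)
})

test_that("spider and waterfall exports are internally consistent", {
  coh <- small_cohort()
  tr <- run_trial(coh, list(regimen("tce", 60, 7, 0)), horizon = 120,
                  bootstrap = FALSE)
  v <- export_views(tr)
  # waterfall sorted descending by best change
  expect_true(all(diff(v$waterfall$best_change_pct) <= 0))
  # spider median trace starts at 0% change, MAD non-negative
  expect_equal(v$spider_summary$median_change[1], 0)
  expect_true(all(v$spider_summary$mad_change >= 0))
  expect_equal(nrow(v$spider), tr$n * length(tr$time))
})

test_that("regimen grid enumerates cells and degenerates correctly", {
  coh <- small_cohort()
  coh$patients <- coh$patients[1:2]
  g <- regimen_grid(coh, tce_doses = c(0, 20, 40, 60),
                    tce_intervals = c(7, 14), apdl1_starts = c(0, 7, 14, 21,
                                                              28),
                    horizon = 60)
  expect_equal(nrow(g), 4 * 2 * 5)    # 40 virtual trials
  expect_true(all(c("median_volume_wk8_cm3", "orr_pct") %in% names(g)))
  # dose-0 engager cells are pure checkpoint monotherapy: identical across
  # engager intervals at the same start day
  z <- g[g$tce_dose_mg == 0 & g$apdl1_start_day == 0, ]
  expect_equal(z$median_volume_wk8_cm3[1], z$median_volume_wk8_cm3[2],
               tolerance = 1e-10)
  expect_error(regimen_grid(coh, numeric(0), 7, 0), "empty")
})
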