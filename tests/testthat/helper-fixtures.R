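# Shared fixtures built once per test run.

# Small screened cohort for trial-engine tests (a dozen draws keeps the
# whole suite fast; the acceptance tests build their own larger cohort).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(N = 16, seed = 5)
    }
    cache
  }
})

# deterministic synthetic diameter series (cm) on a daily grid
diam_series <- function(change_fraction, horizon = 400, baseline = 5) {
  t <- 0:horizon
  d <- baseline * (1 + change_fraction * (t / horizon))
  list(time = t, diameter = d)
}
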