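# Synthetic-data generators and configuration I/O. Every generator is
# deterministic under its seed and stamps the generated object with its
# generating specification.

.fixture_spec <- function(generator, ...) {
  list(generator = generator, params = list(...))
}

#' Synthetic synapse-count vs T-cell-activation data
#'
#' Emulates an in vitro activation assay: log-spaced synapse-per-cell
#' counts with Hill-shaped activation and multiplicative lognormal noise.
#' The numeric assay values behind the shipped activation Hill are not
#' public, so calibration of [fit_activation_hill()] is validated by
#' parameter recovery on this generator.
#'
#' @param K_true,n_true generating Hill half-max and exponent.
#' @param n_points number of points (>= 4).
#' @param noise lognormal sigma of the multiplicative noise (0 = exact).
#' @param seed integer seed.
#' @param span decades of synapse counts around `K_true` to cover.
#' @return data.frame with `synapses`, `activation`, and attribute
#'   `fixture_spec` recording the generator call.
#' @export
gen_activation_data <- function(K_true = 30, n_true = 1.5, n_points = 12,
                                noise = 0, seed = 1, span = 2) {
  if (n_points < 4) stop("n_points must be >= 4")
  set.seed(seed)
  syn <- 10^seq(log10(K_true) - span, log10(K_true) + span,
                length.out = n_points)
  act <- hill(syn, K_true, n_true)
  if (noise > 0) act <- act * exp(stats::rnorm(n_points, 0, noise))
  act <- pmin(pmax(act, 0), 1)
  out <- data.frame(synapses = syn, activation = act)
  attr(out, "fixture_spec") <- .fixture_spec(
    "gen_activation_data", K_true = K_true, n_true = n_true,
    n_points = n_points, noise = noise, seed = seed, span = span)
  out
}

#' Synthetic MuSyC dose-response surface
#'
#' Evaluates the MuSyC two-drug Hill equation ([musyc_effect()]) exactly on
#' a dose grid, with optional multiplicative lognormal noise; the oracle
#' for [fit_musyc()] round-trip tests.
#'
#' @param par MuSyC parameter list (see [musyc_effect()]).
#' @param tce_doses,apdl1_doses dose grids (must include 0).
#' @param noise lognormal sigma (0 = exact).
#' @param seed integer seed.
#' @return a `dose_surface` with attribute `fixture_spec`.
#' @export
gen_musyc_surface <- function(par, tce_doses = c(0, 10, 20, 40, 80),
                              apdl1_doses = c(0, 200, 400, 800, 1600),
                              noise = 0, seed = 1) {
  grid <- expand.grid(d1 = tce_doses, d2 = apdl1_doses)
  set.seed(seed)
  e <- musyc_effect(grid$d1, grid$d2, par)
  if (noise > 0) e <- e * exp(stats::rnorm(length(e), 0, noise))
  E <- matrix(e, length(tce_doses), length(apdl1_doses),
              dimnames = list(tce = tce_doses, apdl1 = apdl1_doses))
  out <- structure(list(tce_doses = tce_doses, apdl1_doses = apdl1_doses,
                        E = E, metric = "synthetic"),
                   class = "dose_surface")
  attr(out, "fixture_spec") <- .fixture_spec(
    "gen_musyc_surface", par = par, tce_doses = tce_doses,
    apdl1_doses = apdl1_doses, noise = noise, seed = seed)
  out
}

#' The shipped default configuration
#'
#' Bundles the baseline parameter set, the sampled virtual-patient ranges
#' and the plausibility screening windows; the unit every acceptance run
#' starts from. Identical to the packaged `extdata/default_config.yaml`.
#'
#' @return list with `params` (`qsp_params`), `ranges` (`param_ranges`),
#'   `screens`.
#' @export
default_config <- function() {
  list(params = default_params(), ranges = default_ranges(),
       screens = default_screens())
}

#' Write a configuration to YAML or JSON
#'
#' @param config list as returned by [default_config()].
#' @param path output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  obj <- list(
    params = as.list(unlist(config$params)),
    units = as.list(param_units(config$params)),
    ranges = lapply(seq_len(nrow(config$ranges)), function(i)
      as.list(config$ranges[i, , drop = FALSE])),
    screens = config$screens)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("unsupported config extension: ", path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#'
#' Validates against the model build: parameter names must match the
#' current parameter table exactly and ranges must be well formed.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration.
#' @return list with `params`, `ranges`, `screens` as in
#'   [default_config()].
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config extension: ", path)
  params <- default_params(overrides = obj$params)
  rng <- do.call(rbind, lapply(obj$ranges, function(r)
    data.frame(name = r$name, lower = as.numeric(r$lower),
               upper = as.numeric(r$upper), scale = r$scale,
               provenance = r$provenance)))
  class(rng) <- c("param_ranges", class(rng))
  .validate_ranges(rng)
  screens <- obj$screens
  screens$blood_T <- as.numeric(screens$blood_T)
  screens$teff_treg <- as.numeric(screens$teff_treg)
  screens$d_tol <- as.numeric(screens$d_tol)
  list(params = params, ranges = rng, screens = screens)
}
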