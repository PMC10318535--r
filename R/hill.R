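#' Hill saturation function
#'
#' The workhorse saturating nonlinearity used throughout the model for
#' activation, killing, suppression and recruitment terms.
#'
#' @param x non-negative stimulus (scalar or vector).
#' @param K positive half-maximal stimulus; `hill(K, K, n) == 0.5`.
#' @param n positive Hill exponent.
#' @return `x^n / (x^n + K^n)`, a fraction in `[0, 1]`, monotone increasing
#'   in `x`.
#' @examples
#' hill(2, 2, 4)        # 0.5 at the half-max
#' hill(0, 1, 2)        # 0 at zero stimulus
#' @export
hill <- function(x, K, n) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("hill(): x must be finite and non-negative")
  }
  if (any(!is.finite(K)) || any(K <= 0) || any(!is.finite(n)) || any(n <= 0)) {
    stop("hill(): K and n must be finite and strictly positive")
  }
  # computed in log space to dodge overflow for large x^n
  r <- (x / K)^n
  ifelse(is.infinite(r), 1, r / (1 + r))
}

#' Tumor cell count to volume and diameter
#'
#' Converts a cancer cell count to tumor volume through the packing density
#' and to the diameter of the volume-equivalent sphere. These are the derived
#' channels reported by trajectories and used for RECIST scoring.
#'
#' @param C cancer cell count (non-negative).
#' @param rho_cell packing density, cells per cm^3.
#' @return list with `volume_cm3` and `diameter_cm`.
#' @export
tumor_volume_and_diameter <- function(C, rho_cell) {
  if (any(C < 0) || any(!is.finite(C))) stop("C must be finite and >= 0")
  if (rho_cell <= 0) stop("rho_cell must be > 0")
  V <- C / rho_cell
  list(volume_cm3 = V, diameter_cm = (6 * V / pi)^(1 / 3))
}

#' @rdname tumor_volume_and_diameter
#' @param d diameter in cm.
#' @return `diameter_to_cells`: the cell count of a spherical tumor of
#'   diameter `d`.
#' @export
diameter_to_cells <- function(d, rho_cell) {
  if (any(d < 0)) stop("d must be >= 0")
  pi / 6 * d^3 * rho_cell
}

# volume (L) of the tumor compartment for a given cell count, floored so
# concentrations stay defined for microscopic tumors
.tumor_volume_L <- function(C, params) {
  max(C / params$rho_cell, 1e-4) / 1000
}
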