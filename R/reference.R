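#' Reference power-polynomial coefficients for the polyethylene standard
#'
#' Published calibration of a 650 nm ellipsoidal-reflector photometer against
#' stacked polyethylene-film light-scattering standards. For each ring of the
#' photometric image (A2, middle; A3, external) the illuminance-thickness
#' model is E_T(d) = m exp(n d) in transmitted light and
#' E_R(d) = a ln(d) + b in reflected light, and each of m, n, a, b is a
#' polynomial in laser power P (mW): degree 2 for m, a, b and degree 6 for n.
#'
#' Coefficients are stored constant-first (`c0` ... `c6`; unused higher
#' orders are `NA`). `r_squared` is the published approximation reliability
#' (coefficient of determination) of each polynomial's fit over the ten
#' power levels 1.8-23.4 mW.
#'
#' @return data.frame with columns `name` (m/n/a/b), `ring` (A2/A3), `mode`,
#'   `degree`, `c0`..`c6`, `r_squared`.
#' @export
reference_power_polynomials <- function() {
  row <- function(name, ring, mode, coeffs, r2) {
    c7 <- rep(NA_real_, 7L)
    c7[seq_along(coeffs)] <- coeffs
    data.frame(name = name, ring = ring, mode = mode,
               degree = length(coeffs) - 1L,
               c0 = c7[1], c1 = c7[2], c2 = c7[3], c3 = c7[4], c4 = c7[5],
               c5 = c7[6], c6 = c7[7], r_squared = r2,
               stringsAsFactors = FALSE)
  }
  n_a2 <- c(-0.1335, -0.0521, 0.0105, -0.0011, 0.00006, -0.000002, 0.00000002)
  n_a3 <- c(-0.1291, -0.0557, 0.0104, -0.0011, 0.00006, -0.000002, 0.00000002)
  rbind(
    row("m", "A2", "transmitted", c(757.62, 1799.9, -32.413), 0.9993),
    row("n", "A2", "transmitted", n_a2, 0.9966),
    row("a", "A2", "reflected", c(1397.1, 383.68, -6.9252), 0.9993),
    row("b", "A2", "reflected", c(109.24, 122.66, -2.3069), 0.9983),
    row("m", "A3", "transmitted", c(-127.22, 1761.9, -25.227), 0.9984),
    row("n", "A3", "transmitted", n_a3, 0.9991),
    row("a", "A3", "reflected", c(-735.69, 687.74, -13.634), 0.9955),
    row("b", "A3", "reflected", c(-29.994, 240.34, -5.7102), 0.9957))
}

#' The laser power grid of the reference study
#'
#' Ten levels from 1.8 mW in steps of 2.4 mW (a 25 mW nominal diode sampled
#' by a stepped power supply).
#'
#' @return numeric vector of powers, mW.
#' @export
reference_power_grid <- function() seq(1.8, by = 2.4, length.out = 10L)
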