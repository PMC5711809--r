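#' Law-of-mass-action binding response
#'
#' Expected titration response at ligand concentration `c` for a 1:1 binding
#' equilibrium between a fluorescently labelled partner at fixed concentration
#' `cfl` and a titrated ligand. The bound fraction of the labelled species is
#' the physical root of the mass-action quadratic,
#' \deqn{f_b = \frac{c_{fl} + c + K_D - \sqrt{(c_{fl}+c+K_D)^2 - 4 c_{fl} c}}
#'   {2 c_{fl}},}
#' and the response interpolates between the unbound plateau `u` (at c = 0)
#' and the bound plateau `b` (at saturation):
#' `response = u + (b - u) * f_b`.
#'
#' The root is evaluated in the conjugate form
#' `f_b = 2 c / (s + sqrt(s^2 - 4 c_fl c))`, `s = c_fl + c + K_D`, which does
#' not suffer catastrophic cancellation at trace ligand concentrations where
#' the naive numerator is a difference of nearly equal large numbers. The
#' bound fraction is clamped to \[0, 1\] against floating-point excursions.
#'
#' @param c Ligand concentration(s) in nM, >= 0. Vectorized.
#' @param kd Dissociation constant in nM, > 0.
#' @param u Response level of the fully unbound labelled species.
#' @param b Response level of the fully bound labelled species. `u == b`
#'   (no binding signal) is allowed.
#' @param cfl Concentration of the labelled partner in nM, > 0.
#' @return Numeric vector of responses, same length as `c`.
#' @examples
#' mass_action_response(c = c(0, 50, 5000, 5e6), kd = 5000, u = 800,
#'                      b = 780, cfl = 50)
#' @export
mass_action_response <- function(c, kd, u, b, cfl) {
  stopifnot(is.numeric(c), all(is.finite(c)),
            is.numeric(kd), length(kd) == 1L, is.finite(kd), kd > 0,
            is.numeric(u), length(u) == 1L, is.finite(u),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(cfl), length(cfl) == 1L, is.finite(cfl), cfl > 0)
  if (any(c < 0)) stop("ligand concentration `c` must be >= 0")
  u + (b - u) * bound_fraction(c, kd, cfl)
}

# Physical root of the binding quadratic, conjugate (cancellation-free) form.
bound_fraction <- function(c, kd, cfl) {
  s <- cfl + c + kd
  disc <- s^2 - 4 * cfl * c   # >= (c - cfl)^2 + kd^2 + 2 kd (c + cfl) > 0
  fb <- 2 * c / (s + sqrt(disc))
  pmin(pmax(fb, 0), 1)
}

#' Binding free energy from the dissociation constant
#'
#' Van't Hoff conversion of a dissociation constant to a standard binding
#' free energy, `dG = R T ln(KD)` with `KD` expressed in molar units against
#' the 1 M reference state. Negative for sub-molar `KD`; lower (more
#' negative) means tighter binding.
#'
#' @param kd Dissociation constant(s) in nM, > 0. Vectorized.
#' @param temperature Absolute temperature in kelvin, > 0. Default 297.15 K
#'   (24 degrees C, a common MST instrument temperature).
#' @return Free energy in kJ/mol.
#' @examples
#' delta_G(10.8e3)  # 10.8 uM -> about -28.3 kJ/mol
#' @export
delta_G <- function(kd, temperature = 297.15) {
  stopifnot(is.numeric(kd), all(is.finite(kd)),
            is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature))
  if (any(kd <= 0)) stop("`kd` must be > 0")
  if (temperature <= 0) stop("`temperature` must be > 0 (kelvin)")
  R_GAS * temperature * log(kd * 1e-9)
}

# Universal gas constant, kJ / (mol K)
R_GAS <- 8.31446261815324e-3
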