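# Single source of physical constants (CODATA 2018) for all field/frequency
# conversions; everything downstream goes through these helpers.
.h_planck <- 6.62607015e-34    # J s
.mu_bohr <- 9.2740100783e-24   # J T^-1

# Point-dipole coupling scale for a g ~ 2 electron pair: nu_dd = 52.04/r^3
# with r in nm and nu in MHz.
.dipolar_mhz_nm3 <- 52.04

#' Physical constants used by the resonance and dipolar calculations
#'
#' @return Named list with the Planck constant `h` (J s), the Bohr magneton
#'   `mu_B` (J/T), and `dipolar_mhz_nm3`, the point-dipole frequency scale
#'   for a g = 2 spin pair (MHz nm^3).
#' @export
#' @examples
#' epr_constants()$dipolar_mhz_nm3
epr_constants <- function() {
  list(h = .h_planck, mu_B = .mu_bohr, dipolar_mhz_nm3 = .dipolar_mhz_nm3)
}

# Resonance field (Gauss) of a spin with effective g at microwave
# frequency nu (GHz): B = h nu / (g mu_B), converted T -> G.
.res_field_gauss <- function(g, nu_ghz) {
  1e4 * .h_planck * nu_ghz * 1e9 / (g * .mu_bohr)
}

# Hyperfine coupling A (MHz) expressed in field units (Gauss) at effective g.
.mhz_to_gauss <- function(a_mhz, g) {
  1e4 * a_mhz * 1e6 * .h_planck / (g * .mu_bohr)
}
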