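#' Physical constants and unit conversions
#'
#' All internal energies are kJ/mol, lengths in Angstrom, masses in amu
#' (g/mol), charges in elementary charges, temperatures in K, pressures in
#' atm. Angular frequencies are rad/s.
#'
#' @name units
#' @keywords internal
NULL

## CODATA 2018 exact values
.const <- list(
  N_A        = 6.02214076e23,        # 1/mol
  kB         = 0.008314462618,       # kJ/mol/K  (gas constant / 1000)
  kB_SI      = 1.380649e-23,         # J/K
  hbar_SI    = 1.054571817e-34,      # J s
  amu        = 1.66053906660e-27,    # kg
  e_charge   = 1.602176634e-19,      # C
  epsilon0   = 8.8541878128e-12      # F/m
)

## hbar in kJ s / mol, so hbar * omega[rad/s] is kJ/mol directly
.const$hbar <- .const$hbar_SI * .const$N_A / 1000

## Coulomb prefactor: q1*q2/r with q in e, r in Angstrom -> kJ/mol
.const$coulomb <- .const$e_charge^2 * .const$N_A /
  (4 * pi * .const$epsilon0 * 1e-10) / 1000

## mass-weighted Hessian eigenvalue lambda [kJ/mol/A^2/amu] -> omega^2 [s^-2]
.const$lambda_to_omega2 <- 1000 / (.const$N_A * .const$amu * 1e-20)

## P[atm] * V[A^3] per molecule -> kJ/mol
.const$atmA3_to_kJmol <- 101325 * 1e-30 * .const$N_A / 1000

#' Convert mass-weighted Hessian eigenvalues to angular frequencies
#'
#' Eigenvalues of the dynamical matrix carry units of kJ/mol/A^2/amu; the
#' corresponding phonon angular frequency is the square root after
#' conversion to SI. Negative eigenvalues (imaginary modes) map to negative
#' "frequencies" `-sqrt(-lambda)` so instability is preserved in the sign.
#'
#' @param lambda numeric vector of mass-weighted eigenvalues
#'   (kJ/mol/A^2/amu).
#' @return numeric vector of angular frequencies (rad/s), negative for
#'   unstable modes.
#' @examples
#' omega_from_lambda(1)    # ~1e13 rad/s
#' @export
omega_from_lambda <- function(lambda) {
  sign(lambda) * sqrt(abs(lambda) * .const$lambda_to_omega2)
}

## standard atomic masses (g/mol) for fixture elements
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Cl = 35.45, S = 32.06, P = 30.974, Ar = 39.948,
  X = 1.0
)

element_mass <- function(symbol) {
  m <- .element_masses[symbol]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
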