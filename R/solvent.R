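#' Debye-Hueckel screening parameter from ionic strength
#'
#' Computes the inverse Debye length \eqn{\kappa} of a 1:1 electrolyte from
#' the ionic strength, solvent dielectric and temperature, using the closed
#' form \eqn{\kappa^2 = 2 N_A e^2 (1000 I) / (\epsilon_0 \epsilon_r k_B T)}
#' evaluated in SI units and converted to inverse Angstrom.
#'
#' @param ionic_strength ionic strength, mol/L.
#' @param eps relative dielectric constant of the solvent.
#' @param temperature temperature, K.
#' @return \eqn{\kappa} in 1/Angstrom.
#' @examples
#' debye_kappa(0.1)           # ~0.103 1/A in water at 300 K
#' @export
debye_kappa <- function(ionic_strength, eps = 80, temperature = 300) {
  stopifnot(is.numeric(ionic_strength), ionic_strength >= 0,
            eps >= 1, temperature > 0)
  e_charge <- 1.602176634e-19   # C
  avogadro <- 6.02214076e23     # 1/mol
  eps0     <- 8.8541878128e-12  # F/m
  k_boltz  <- 1.380649e-23      # J/K
  number_density <- 1000 * ionic_strength * avogadro  # ions per m^3
  kappa_m <- sqrt(2 * number_density * e_charge^2 /
                    (eps0 * eps * k_boltz * temperature))
  kappa_m * 1e-10
}

#' Implicit-solvent model constants
#'
#' Bundles the constants of the continuum-solvent description: the solvent
#' and solute dielectrics, the Debye-Hueckel screening parameter (derived
#' from the ionic strength unless given explicitly), the surface-tension
#' coefficient and offset of the nonpolar term, and the solvent probe radius.
#'
#' @param eps_solvent relative solvent dielectric (80 for water).
#' @param eps_solute relative solute-interior dielectric.
#' @param ionic_strength mol/L; used to derive `kappa` when `kappa` is `NULL`.
#' @param kappa inverse Debye length, 1/Angstrom; overrides `ionic_strength`.
#' @param temperature K, used in the Debye-Hueckel relation.
#' @param gamma surface tension of the nonpolar term, kcal/(mol*Angstrom^2).
#' @param beta_offset constant offset of the nonpolar term, kcal/mol.
#' @param probe_radius solvent probe radius, Angstrom.
#' @param coulomb_constant electrostatic conversion, kcal*A/(mol*e^2).
#' @return An object of class `solvent_model`.
#' @export
solvent_model <- function(eps_solvent = 80, eps_solute = 1,
                          ionic_strength = 0.1, kappa = NULL,
                          temperature = 300,
                          gamma = 0.0072, beta_offset = 0,
                          probe_radius = 1.4,
                          coulomb_constant = COULOMB_K) {
  if (!(eps_solvent > eps_solute && eps_solute >= 1))
    stop("solvent_model: require eps_solvent > eps_solute >= 1")
  if (is.null(kappa))
    kappa <- debye_kappa(ionic_strength, eps = eps_solvent,
                         temperature = temperature)
  if (kappa < 0) stop("solvent_model: kappa must be >= 0")
  structure(list(eps_solvent = eps_solvent, eps_solute = eps_solute,
                 ionic_strength = ionic_strength, kappa = kappa,
                 temperature = temperature, gamma = gamma,
                 beta_offset = beta_offset, probe_radius = probe_radius,
                 coulomb_constant = coulomb_constant),
            class = "solvent_model")
}

#' @export
print.solvent_model <- function(x, ...) {
  cat("Implicit-solvent model\n")
  cat(sprintf("  dielectrics     : solvent %.1f / solute %.2f\n",
              x$eps_solvent, x$eps_solute))
  cat(sprintf("  ionic strength  : %.3f M (kappa = %.5f 1/A)\n",
              x$ionic_strength, x$kappa))
  cat(sprintf("  nonpolar        : gamma = %.4f kcal/(mol*A^2), beta = %.3f\n",
              x$gamma, x$beta_offset))
  cat(sprintf("  probe radius    : %.2f A\n", x$probe_radius))
  invisible(x)
}
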