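#' Physical constants for PB electrostatics
#'
#' Derives the unit-system constants used throughout the solver from
#' CODATA values: potentials are carried in kT/e, lengths in Angstrom,
#' charges in units of the elementary charge; energies are converted to
#' kcal/mol only at reporting time.
#'
#' \describe{
#'   \item{coulombKcal}{e^2/(4 pi eps0) expressed in kcal*Angstrom/(mol*e^2),
#'     about 332.06; the familiar Coulomb-law constant.}
#'   \item{kTKcalMol}{k_B*T in kcal/mol (0.59616 at 300 K).}
#'   \item{coulombPrefactor}{e^2/(4 pi eps0 k_B T * 1 Angstrom) in
#'     (kT/e) units: the potential of a unit charge at 1 Angstrom in a
#'     unit dielectric.}
#'   \item{kappa2}{Debye-Huckel parameter kappa^2 = 8 pi C n, 1/Angstrom^2,
#'     where n is the total ion number density for a 1:1 salt of molar
#'     strength I; divide by eps_out before taking the screening length.}
#' }
#'
#' @param temperature absolute temperature, K.
#' @param saltMolar ionic strength I, mol/L (1:1 salt assumed).
#' @return named list with the entries described above plus the inputs.
#' @examples
#' pc <- physicalConstants(300, 0.145)
#' sqrt(80 / pc$kappa2)   # Debye screening length in water, ~8 A
#' @export
physicalConstants <- function(temperature = 300, saltMolar = 0) {
  stopifnot(temperature > 0, saltMolar >= 0)
  eC <- 1.602176634e-19        # C
  eps0 <- 8.8541878128e-12     # F/m
  kB <- 1.380649e-23           # J/K
  nA <- 6.02214076e23          # 1/mol
  calJ <- 4184                 # J/kcal
  coulombJm <- eC^2 / (4 * pi * eps0)             # J*m
  coulombKcal <- coulombJm * 1e10 * nA / calJ     # kcal*A/mol
  kTKcalMol <- kB * temperature * nA / calJ       # kcal/mol
  coulombPrefactor <- coulombJm * 1e10 / (kB * temperature)  # kT/e * A
  # ion number density per A^3 for 1:1 salt: 2 * N_A * I / 1e27
  nIon <- 2 * nA * saltMolar / 1e27
  kappa2 <- 4 * pi * coulombPrefactor * nIon      # 1/A^2
  list(coulombKcal = coulombKcal, kTKcalMol = kTKcalMol,
       coulombPrefactor = coulombPrefactor, kappa2 = kappa2,
       temperature = temperature, saltMolar = saltMolar)
}

#' Debye-Huckel screening parameter
#'
#' kappa^2 = (2 N_A e^2 / 1000 k_B T) * I expressed per Angstrom^2 in
#' the solver's reduced units. Linear in the ionic strength and zero at
#' I = 0. The screening length in a medium of dielectric eps_out is
#' sqrt(eps_out / kappa^2).
#'
#' @param saltMolar ionic strength I, mol/L.
#' @param temperature absolute temperature, K.
#' @return kappa^2 in 1/Angstrom^2 (dielectric not yet divided out).
#' @examples
#' debyeKappa2(0.145, 300)
#' @export
debyeKappa2 <- function(saltMolar, temperature = 300) {
  physicalConstants(temperature, saltMolar)$kappa2
}
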