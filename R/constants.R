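#' Physical constants in MD units
#'
#' The package works in GROMACS-style molecular-dynamics units throughout:
#' lengths in nm, times in ps, energies in kJ/mol, charges in units of the
#' elementary charge e, temperatures in K.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kJ/mol/K (equals the molar gas constant R).}
#'   \item{kC}{Coulomb constant e^2/(4 pi eps0), kJ mol^-1 nm e^-2.}
#'   \item{NA_mol}{Avogadro's number, mol^-1.}
#'   \item{e_over_eps0}{e / eps0 expressed as V nm per (e nm^-2); converts a
#'     surface charge density in e/nm^2 into an electric field in V/nm.}
#' }
#' @examples
#' md_constants$kB * 300  # thermal energy at 300 K, kJ/mol
#' @export
md_constants <- list(
  kB          = 0.008314462618,
  kC          = 138.935458,
  NA_mol      = 6.02214076e23,
  e_over_eps0 = 18.09512632
)

#' @keywords internal
.kB <- md_constants$kB

#' @keywords internal
.kC <- md_constants$kC
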