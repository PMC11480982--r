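#' @useDynLib coronaforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx integrate runif rnorm setNames sd
#' @importFrom utils read.table write.table
NULL

## Physical constants. Energies are carried in kJ/mol inside the potential
## stack and converted to kBT at the configured temperature at the module
## boundaries (free-energy integration, KMC rates).
.kB_kJmol <- 0.0083144626   # Boltzmann constant, kJ mol^-1 K^-1
.emV_kJmol <- 0.0964853     # 1 e.mV in kJ mol^-1 (Faraday constant / 1e6)
.kJmol_J <- 1.6605778e-21   # 1 kJ mol^-1 per molecule, in J
.N_A <- 6.02214076e23       # Avogadro
.h_planck <- 6.62607015e-34 # J s
.kB_J <- 1.380649e-23       # J K^-1
.water_viscosity <- 8.9e-4  # Pa s at 25 C
.wall_cap_kT <- 1e6         # cap on the short-range stability wall

#' Thermal energy
#'
#' Boltzmann constant times temperature in kJ/mol. At the default 300 K this
#' is 2.494 kJ/mol.
#'
#' @param temperature Temperature in K.
#' @return Thermal energy in kJ/mol.
#' @export
kBT_kJmol <- function(temperature = 300) .kB_kJmol * temperature

#' Energy unit conversions for Hamaker constants
#'
#' Hamaker files store constants in kJ/mol for consistency with the tabulated
#' surface potentials; the literature usually quotes them in J (per molecule
#' pair). `1 kJ/mol = 1.6606e-21 J`.
#'
#' @param x Energy value(s).
#' @return Converted value(s).
#' @export
kJmol_to_J <- function(x) x * .kJmol_J

#' @rdname kJmol_to_J
#' @export
J_to_kJmol <- function(x) x / .kJmol_J

## Default per-residue charges (elementary charges) at pH 7. HIS carries the
## fractional charge of the preaveraged bead; protonation variants alias to it.
.residue_charges <- c(
  ARG = 1, LYS = 1, ASP = -1, GLU = -1, HIS = 0.1
)

## Residue-code aliases applied on read (protonation-state variants).
.residue_aliases <- c(
  HIE = "HIS", HID = "HIS", HIP = "HIS",
  CYX = "CYS", GLH = "GLU", ASH = "ASP", LYN = "LYS", ARN = "ARG"
)

#' Default bead charge lookup
#'
#' Charge in elementary units assigned to a bead code: +1 for ARG/LYS, -1 for
#' ASP/GLU, +0.1 for the pH-7 preaveraged HIS bead, 0 otherwise.
#'
#' @param codes Character vector of bead codes.
#' @return Numeric vector of charges in e.
#' @export
bead_charge <- function(codes) {
  codes <- normalize_bead_code(codes)
  ch <- .residue_charges[codes]
  ch[is.na(ch)] <- 0
  unname(ch)
}

#' Canonical bead code
#'
#' Upper-cases and maps protonation-state aliases (HIE/HID/HIP and similar)
#' onto their parent residue code.
#'
#' @param codes Character vector.
#' @return Character vector of canonical codes.
#' @export
normalize_bead_code <- function(codes) {
  codes <- toupper(trimws(codes))
  hit <- codes %in% names(.residue_aliases)
  codes[hit] <- .residue_aliases[codes[hit]]
  codes
}

## Twenty standard residue codes, used as default synthetic bead codes so toy
## biomolecules resolve against synthetic materials.
.standard_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

`%||%` <- function(a, b) if (is.null(a)) b else a
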