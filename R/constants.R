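## Physical constant tables used across the package. All masses are average
## (not monoisotopic) masses in Da, appropriate for native MS of large
## non-covalent complexes; radii are in Angstrom.

#' Average atomic masses of the elements handled by the package
#'
#' Standard atomic weights (IUPAC 2021, rounded to 3-4 decimals) for the
#' elements that occur in protein/nucleic-acid models and common ligands.
#' Center-of-mass calculations reject elements absent from this table at
#' parse time.
#'
#' @format Named numeric vector, Da per atom.
#' @export
atomicMasses <- c(
  H = 1.008,  C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, MN = 54.938,
  CA = 40.078, `NA` = 22.990, K = 39.098, CL = 35.45, F = 18.998,
  BR = 79.904, I = 126.904, CU = 63.546, NI = 58.693, CO = 58.933,
  MO = 95.95, W = 183.84
)

#' Van der Waals radii
#'
#' Bondi (1964) radii for the common elements of macromolecular models,
#' with 1.80 A for phosphorus and a 1.70 A fallback used for metals when a
#' sphere must be drawn around an ion. Used by the accessible-surface and
#' chamber-diameter routines.
#'
#' @format Named numeric vector, Angstrom.
#' @export
vdwRadii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  FE = 1.70, ZN = 1.39, MG = 1.73, MN = 1.70, CA = 1.70, `NA` = 2.27,
  K = 2.75, CU = 1.40, NI = 1.63, CO = 1.70, MO = 1.70, W = 1.70
)

## Average residue masses (Da) of the 20 standard amino acids as chain
## residues (monomer minus water). Summing over a sequence and adding one
## water gives the average mass of the free polypeptide.
aaResidueMasses <- c(
  G = 57.0513, A = 71.0779, S = 87.0773, P = 97.1152, V = 99.1311,
  T = 101.1039, C = 103.1429, L = 113.1576, I = 113.1576, N = 114.1026,
  D = 115.0874, Q = 128.1292, K = 128.1723, E = 129.1140, M = 131.1961,
  H = 137.1393, F = 147.1739, R = 156.1857, Y = 163.1733, W = 186.2099
)

## Average residue masses (Da) of 2'-deoxyribonucleotide-5'-monophosphate
## chain residues (nucleoside-5'-monophosphate minus water). Summing over a
## sequence and adding one water yields a 5'-phosphate/3'-OH single strand.
dnaResidueMasses <- c(
  A = 313.2058, C = 289.1815, G = 329.2052, T = 304.1926
)

waterMass <- 18.0153   # H2O, average
hpo3Mass  <- 79.9799   # metaphosphate HPO3, the 5'/3' terminal phosphate unit
protonMass <- 1.00728  # charge carrier for positive-mode electrospray

## The 43-mer single strand derived from the A/T-rich DNA unwinding element
## of the lambda replication origin, used in the binding and native-MS
## experiments the package's mass arithmetic reproduces.
#' @export
oriLambdaDUE43 <- "TGACGAATAATCTTTTCTTTTTTCTTTTGTAATAGTGTCTTTT"

## Printed average monomer masses (Da) of the assembly components as used by
## the native-MS stoichiometry defaults: DnaB protomer (N-terminal Met loss),
## lambda P loader protomer, and the 43-mer origin-derived ssDNA (5'/3'-OH).
defaultComponentMasses <- c(DnaB = 52259, lambdaP = 26518, ssDNA = 13141)
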