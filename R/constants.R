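# Physical constants and unit conversions (internal).
#
# Energies are kcal/mol, lengths Angstrom, masses amu, times ps throughout.
# 1 kcal/mol = 4184 J/mol = 418.4 amu A^2 ps^-2, so accelerations are
# F [kcal/mol/A] * .KCAL_TO_AKMA / m [amu] in A ps^-2.

.KB_KCAL <- 0.0019872041      # Boltzmann constant, kcal mol^-1 K^-1
.KCAL_TO_AKMA <- 418.4        # kcal/mol -> amu A^2 ps^-2
.B_FROM_MSF <- 8 * pi^2 / 3   # B = (8 pi^2 / 3) <dr^2>

# Average residue masses (monomer minus water), amu. Unknown types fall
# back to 110 amu, the canonical average residue mass.
.RESIDUE_MASS <- c(
  GLY = 57.05,  ALA = 71.08,  SER = 87.08,  PRO = 97.12,  VAL = 99.13,
  THR = 101.10, CYS = 103.14, LEU = 113.16, ILE = 113.16, ASN = 114.10,
  ASP = 115.09, GLN = 128.13, LYS = 128.17, GLU = 129.12, MET = 131.19,
  HIS = 137.14, PHE = 147.18, ARG = 156.19, TYR = 163.18, TRP = 186.21
)
.MASS_FALLBACK <- 110

residueMass <- function(resname) {
  m <- .RESIDUE_MASS[toupper(resname)]
  m[is.na(m)] <- .MASS_FALLBACK
  unname(m)
}

# Flatten N x 3 coordinates to the 3N vector (x1,y1,z1,x2,...) and back.
.flatten <- function(coords) as.numeric(t(coords))
.unflatten <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

.pairDist <- function(coords, i, j) {
  sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
}
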