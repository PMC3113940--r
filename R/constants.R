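# Amino-acid reference data and geometric constants used across the package.
# All tables are shipped as plain R constants so that every derived quantity
# is reproducible from source alone.

#' Standard amino-acid alphabet
#'
#' One-letter codes of the 20 standard amino acids, in alphabetical order.
#' This ordering defines the `s` descriptor index used by all potential
#' tables.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# three-letter -> one-letter lookup (standard residues only)
AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y"
)

AA_ONE_TO_THREE <- structure(names(AA_THREE_TO_ONE), names = AA_THREE_TO_ONE)

#' Mean residue volumes
#'
#' Mean volumes of the 20 amino-acid residues in folded proteins
#' (Chothia, Nature 254:304, 1975), in cubic Angstrom.  Used for the
#' cavity/accommodation volume terms `dV+` and `dV-`.
#'
#' @format Named numeric vector (one-letter codes), Angstrom^3.
#' @export
AA_VOLUMES <- c(
  A =  88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
  Q = 143.8, E = 138.4, G =  60.1, H = 153.2, I = 166.7,
  L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
  S =  89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0
)

# Reference (maximal) solvent-accessible surface areas of residue X in an
# extended Gly-X-Gly tripeptide, Angstrom^2 (theoretical values of Tien et
# al., PLoS ONE 8:e80635, 2013).  Relative accessibility = SASA / reference.
AA_REF_SASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

# van der Waals radii by element, Angstrom (Bondi-style); the fallback is
# used for pseudo-atoms and uncommon elements.
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                   P = 1.80, SE = 1.90)
ELEMENT_RADIUS_DEFAULT <- 1.70

# Water-probe radius for solvent accessibility, Angstrom.
SASA_PROBE_RADIUS <- 1.4
# Sphere sample points per atom (Fibonacci lattice).
SASA_N_POINTS <- 960L

#' Torsion-domain alphabet
#'
#' Discrete labels for the backbone (phi, psi) conformational state:
#' `A` helical, `B` extended, `P` polyproline-II, `L` left-handed helical,
#' `G` gamma, `E` epsilon, `O` other, `U` undefined (chain termini or
#' missing backbone atoms).
#'
#' @format Character vector of length 8.
#' @export
TORSION_ALPHABET <- c("A", "B", "P", "L", "G", "E", "O", "U")

# Ramachandran-plane partition used by assign_torsion_domain().  Boxes are
# checked in order; the first match wins; anything unmatched is "O".
# Angles in degrees, phi/psi in [-180, 180].  Boundary convention:
# lower bound inclusive, upper bound exclusive.
TORSION_DOMAINS <- list(
  A = list(phi = c(-160,  -20), psi = c( -90,  45)),  # alpha-helical
  B = list(phi = c(-180,  -90), psi = c(  90, 181)),  # extended / beta
  B2 = list(phi = c(-180, -90), psi = c(-181, -150), label = "B"),
  P = list(phi = c( -90,  -20), psi = c(  90, 181)),  # polyproline II
  L = list(phi = c(   0,  120), psi = c( -60,  90)),  # left-handed helical
  G = list(phi = c(   0,  120), psi = c(  90, 181)),  # gamma
  E = list(phi = c(  20,  180), psi = c(-180, -30))   # epsilon
)

# Minimal sequence separation |i - j| for a residue pair to enter the
# distance map (and hence the distance potentials).
MIN_SEQ_SEPARATION <- 2L

# Default centroid-distance window for distance potentials, Angstrom.
DISTANCE_LOWER <- 3.0
DISTANCE_UPPER <- 8.0

# Energy scale kT at T = 298 K, kcal/mol.
KT_KCAL_MOL <- 0.593

# Default relative-accessibility bin boundaries (percent) for the `a`
# descriptor: 5 bins.
ACC_BIN_BREAKS <- c(0, 5, 15, 30, 50, 100)

# The 13 statistical-potential term identifiers, in canonical order.
POTENTIAL_TERMS <- c("st", "as", "sd", "sds", "stt", "sst", "aas",
                     "ass", "ast", "asd", "std", "asdas", "stdst")
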