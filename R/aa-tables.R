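#' Amino-acid descriptor and constant tables
#'
#' Constant tables used throughout the signal-peptide feature calculations:
#' Kyte-Doolittle hydropathy, the three principal-property z-scales
#' (z1 hydrophobicity/hydrophilicity, z2 side-chain volume/bulk, z3
#' polarizability/electronic character), average residue masses, and the
#' Bjellqvist-style pKa set used by ProtParam-type charge calculators.
#'
#' @name aa_tables
#' @keywords internal
NULL

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte & Doolittle hydropathy index
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Principal-property z-scales for the 20 amino acids (dimensionless).
# Lower z1 = more hydrophobic; z2 tracks side-chain bulk; z3 electronic
# properties/polarizability.
ZSCALES <- data.frame(
  aa = c("A", "V", "L", "I", "P", "F", "W", "M", "K", "R",
         "H", "G", "S", "T", "C", "Y", "N", "Q", "D", "E"),
  z1 = c( 0.07, -2.69, -4.19, -4.44, -1.22, -4.92, -4.75, -2.49,  2.84,  2.88,
          2.41,  2.23,  1.96,  0.92,  0.71, -1.39,  3.22,  2.18,  3.64,  3.08),
  z2 = c(-1.73, -2.53, -1.03, -1.68,  0.88,  1.30,  3.65, -0.27,  1.41,  2.52,
          1.74, -5.36, -1.63, -2.09, -0.97,  2.32,  1.45,  0.53,  1.13,  0.39),
  z3 = c( 0.09, -1.29, -0.98, -1.03,  2.23,  0.45,  0.85, -0.41, -3.14, -3.44,
          1.11,  0.30,  0.57, -1.40,  4.13,  0.01,  0.84, -1.14,  2.36, -0.07),
  stringsAsFactors = FALSE)
rownames(ZSCALES) <- ZSCALES$aa

# Average masses of the free amino acids (Da); peptide MW subtracts one
# water (18.01528 Da) per peptide bond.
AA_MASS <- c(
  A =  89.0935, R = 174.2017, N = 132.1184, D = 133.1032, C = 121.1590,
  Q = 146.1451, E = 147.1293, G =  75.0669, H = 155.1552, I = 131.1736,
  L = 131.1736, K = 146.1882, M = 149.2124, F = 165.1900, P = 115.1310,
  S = 105.0930, T = 119.1197, W = 204.2262, Y = 181.1894, V = 117.1469)

H2O_MASS <- 18.01528

# Bjellqvist-style pKa set (ProtParam-like).  A single N-terminal pKa is
# used for all residues.
PKA_POSITIVE <- c(Nterm = 7.50, K = 10.00, R = 12.00, H = 5.98)
PKA_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00)

#' z-scale descriptor table
#'
#' Returns the three-descriptor principal-property table for the 20 standard
#' amino acids.  z1 corresponds to hydrophobicity/hydrophilicity (lower is
#' more hydrophobic), z2 to side-chain volume/bulk, and z3 to
#' polarizability/electronic properties.
#'
#' @return A data.frame with columns `aa`, `z1`, `z2`, `z3` (20 rows).
#' @export
#' @examples
#' head(zscale_table())
zscale_table <- function() {
  ZSCALES
}

#' Kyte-Doolittle hydropathy values
#'
#' @return Named numeric vector of hydropathy values for the 20 amino acids.
#' @export
kd_hydropathy <- function() {
  KD_HYDROPATHY
}

# split a sequence into residue letters, validating the alphabet
.residues <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("sequence must be a single non-empty string")
  r <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(r), AA_LETTERS)
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  r
}
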