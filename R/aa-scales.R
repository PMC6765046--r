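# Amino-acid physicochemical property tables used by the pseudo-amino-acid
# composition and Moran autocorrelation descriptors. All tables cover the 20
# standard residues in the fixed alphabet order used throughout the package.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA_ALPHABET <- c("A", "C", "G", "T")

.aa_scale <- function(...) {
  x <- c(...)
  stopifnot(setequal(names(x), AA_ALPHABET))
  x[AA_ALPHABET]
}

# Kyte-Doolittle hydropathy index.
AA_HYDROPHOBICITY <- .aa_scale(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Hopp-Woods hydrophilicity values.
AA_HYDROPHILICITY <- .aa_scale(
  A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2, E = 3.0,
  G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3, F = -2.5,
  P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5)

# Side-chain mass (Da).
AA_SIDECHAIN_MASS <- .aa_scale(
  A = 15.0, R = 101.0, N = 58.0, D = 59.0, C = 47.0, Q = 72.0, E = 73.0,
  G = 1.0, H = 82.0, I = 57.0, L = 57.0, K = 73.0, M = 75.0, F = 91.0,
  P = 42.0, S = 31.0, T = 45.0, W = 130.0, Y = 107.0, V = 43.0)

# Residue molecular weight (Da).
AA_RESIDUE_WEIGHT <- .aa_scale(
  A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.15, Q = 146.15,
  E = 147.13, G = 75.07, H = 155.16, I = 131.17, L = 131.17, K = 146.19,
  M = 149.21, F = 165.19, P = 115.13, S = 105.09, T = 119.12, V = 117.15,
  W = 204.23, Y = 181.19)

# pK of the alpha-carboxyl group.
AA_PK_COOH <- .aa_scale(
  A = 2.34, R = 2.17, N = 2.02, D = 1.88, C = 1.96, Q = 2.17, E = 2.19,
  G = 2.34, H = 1.82, I = 2.36, L = 2.36, K = 2.18, M = 2.28, F = 1.83,
  P = 1.99, S = 2.21, T = 2.09, V = 2.32, W = 2.38, Y = 2.20)

# pK of the alpha-amino group.
AA_PK_NH3 <- .aa_scale(
  A = 9.69, R = 9.04, N = 8.80, D = 9.60, C = 10.28, Q = 9.13, E = 9.67,
  G = 9.60, H = 9.17, I = 9.68, L = 9.60, K = 8.95, M = 9.21, F = 9.13,
  P = 10.60, S = 9.15, T = 9.10, V = 9.62, W = 9.39, Y = 9.11)

# Isoelectric point.
AA_PI <- .aa_scale(
  A = 6.00, R = 10.76, N = 5.41, D = 2.77, C = 5.07, Q = 5.65, E = 3.22,
  G = 5.97, H = 7.59, I = 6.02, L = 5.98, K = 9.74, M = 5.74, F = 5.48,
  P = 6.30, S = 5.68, T = 5.60, V = 5.96, W = 5.89, Y = 5.66)

# Residue volume (A^3, Zamyatnin).
AA_VOLUME <- .aa_scale(
  A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, Q = 143.8,
  E = 138.4, G = 60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
  M = 162.9, F = 189.9, P = 112.7, S = 89.0, T = 116.1, V = 140.0,
  W = 227.8, Y = 193.6)

#' Default property scales for the pseudo-amino-acid composition
#'
#' Hydrophobicity (Kyte-Doolittle), hydrophilicity (Hopp-Woods) and
#' side-chain mass: the canonical triple for Chou-type pseudo-amino-acid
#' composition.
#'
#' @return Named list of three numeric vectors, each covering the 20
#'   standard residues.
#' @export
paac_default_scales <- function() {
  list(hydrophobicity = AA_HYDROPHOBICITY,
       hydrophilicity = AA_HYDROPHILICITY,
       sidechain_mass = AA_SIDECHAIN_MASS)
}

#' Default property scales for Moran autocorrelation
#'
#' Eight standard physicochemical residue scales: hydrophobicity,
#' hydrophilicity, side-chain mass, residue molecular weight, the two
#' alpha-group pK values, isoelectric point and residue volume. Each is
#' standardized (zero mean, unit variance over the 20 residues) before use;
#' Moran autocorrelation is invariant to affine rescaling of the property,
#' so the standardization only fixes a convention.
#'
#' @return Named list of eight numeric vectors over the 20 standard residues.
#' @export
moran_default_scales <- function() {
  list(hydrophobicity = AA_HYDROPHOBICITY,
       hydrophilicity = AA_HYDROPHILICITY,
       sidechain_mass = AA_SIDECHAIN_MASS,
       residue_weight = AA_RESIDUE_WEIGHT,
       pk_cooh        = AA_PK_COOH,
       pk_nh3         = AA_PK_NH3,
       isoelectric    = AA_PI,
       volume         = AA_VOLUME)
}
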