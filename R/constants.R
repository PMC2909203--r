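# Shared residue-level lookup tables. All masses in Da, lengths in Angstrom.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Average (isotope-abundance weighted) residue masses; free chain adds one water.
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.02

# Eisenberg consensus hydrophobicity scale.
EISENBERG <- c(
  A = 0.62,  R = -2.53, N = -0.78, D = -0.90, C = 0.29,
  Q = -0.85, E = -0.74, G = 0.48,  H = -0.40, I = 1.38,
  L = 1.06,  K = -1.50, M = 0.64,  F = 1.19,  P = 0.12,
  S = -0.18, T = -0.05, W = 0.81,  Y = 0.26,  V = 1.08)

HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "C")
POSITIVE_AA <- c("K", "R")
NEGATIVE_AA <- c("D", "E")

# Coarse residue classes used for reduced CB atom typing and fixture design.
residueClass <- function(aa) {
  ifelse(aa %in% HYDROPHOBIC_AA, "hyd",
         ifelse(aa %in% POSITIVE_AA, "pos",
                ifelse(aa %in% NEGATIVE_AA, "neg", "pol")))
}

# van der Waals radii by element (soft-sphere and SASA calculations).
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

elementOf <- function(atom_name) {
  first <- substr(gsub("[0-9]", "", atom_name), 1, 1)
  ifelse(first %in% names(VDW_RADII), first, "C")
}

atomRadius <- function(atom_name) {
  unname(VDW_RADII[elementOf(atom_name)])
}

# Atomic solvation parameters for the desolvation patch score, by atom class
# (apolar carbon favorable to desolvate = negative; polar/charged unfavorable).
# Units: score per A^2 of SASA; a simplified octanol/water-style table.
ASP_TABLE <- c(
  C_apolar  = -0.012,   # CA/C/CB carbons of apolar residues
  C_polar   = -0.004,   # carbons of polar/charged residues
  N_backbone = 0.006,
  O_backbone = 0.008,
  CB_charged = 0.015)   # CB standing in for a charged sidechain

# Ideal backbone covalent geometry (lengths A, angles degrees).
GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.5, a_c_ca_cb = 110.5,
  omega = 180)

HELIX_PHI <- -57
HELIX_PSI <- -47
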