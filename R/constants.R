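# Physicochemical constant tables used by the sequence calculators.
#
# Provenance:
#  - KD_HYDROPATHY: Kyte & Doolittle (1982) J Mol Biol 157:105-132.
#  - DIWV: dipeptide instability weight values, Guruprasad, Reddy & Pandit
#    (1990) Protein Eng 4:155-161 (the table used by ExPASy ProtParam).
#  - PKA_*: Bjellqvist et al. (1993) Electrophoresis 14:1023-1031, the pKa
#    set used by ExPASy ProtParam for theoretical pI.
#  - RESIDUE_FORMULA: molecular formulas of the free amino acids; chain
#    composition is the residue sum minus (L-1) waters.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# rows: N-terminal residue of the dipeptide; columns: C-terminal residue
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(AA_STANDARD, AA_STANDARD))

# Bjellqvist pKa values (side chains and termini). Terminal pKa depends on
# the terminal residue for the listed exceptions.
PKA_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PKA_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PKA_NTERM_BY_RESIDUE <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                          V = 7.44, E = 7.7)
PKA_CTERM_BY_RESIDUE <- c(D = 4.55, E = 4.75)

# Free amino-acid molecular formulas, atom counts in order C, H, N, O, S.
RESIDUE_FORMULA <- matrix(c(
  3,  7, 1, 2, 0,   # A
  3,  7, 1, 2, 1,   # C
  4,  7, 1, 4, 0,   # D
  5,  9, 1, 4, 0,   # E
  9, 11, 1, 2, 0,   # F
  2,  5, 1, 2, 0,   # G
  6,  9, 3, 2, 0,   # H
  6, 13, 1, 2, 0,   # I
  6, 14, 2, 2, 0,   # K
  6, 13, 1, 2, 0,   # L
  5, 11, 1, 2, 1,   # M
  4,  8, 2, 3, 0,   # N
  5,  9, 1, 2, 0,   # P
  5, 10, 2, 3, 0,   # Q
  6, 14, 4, 2, 0,   # R
  3,  7, 1, 3, 0,   # S
  4,  9, 1, 3, 0,   # T
  5, 11, 1, 2, 0,   # V
 11, 12, 2, 2, 0,   # W
  9, 11, 1, 3, 0    # Y
), nrow = 20, byrow = TRUE,
  dimnames = list(AA_STANDARD, c("C", "H", "N", "O", "S")))

# Aliphatic index side-chain volume coefficients (Ikai 1980)
ALIPHATIC_COEF <- c(A = 1, V = 2.9, I = 3.9, L = 3.9)

TIME_LEVELS <- c("T1", "T2", "T3")
COMPARISONS <- c("T1vT2", "T2vT3", "T1vT3")

PROFILE_CATEGORIES <- c(
  "secondary_cement_production_I", "secondary_cement_production_II",
  "cement_maintenance", "feeding", "feeding_and_oogenesis",
  "molting", "detachment", "housekeeping"
)
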