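# Shared vocabularies and group registries (loaded before the other files).

AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

AA1 <- setNames(names(AA3), unname(AA3))

DNA_RES <- c(DA = "A", DC = "C", DG = "G", DT = "T", DI = "I")
RNA_RES <- c(A = "A", C = "C", G = "G", U = "U", I = "I")

# number of sidechain heavy atoms per amino acid (standard residues)
AA_SIDECHAIN_N <- c(
  A = 1L, R = 7L, N = 4L, D = 4L, C = 2L, Q = 5L, E = 5L, G = 0L, H = 6L,
  I = 4L, L = 4L, K = 5L, M = 4L, F = 7L, P = 3L, S = 2L, T = 3L, W = 10L,
  Y = 8L, V = 3L
)

# BLOSUM62 background amino-acid frequencies (sums to 1)
BLOSUM62_BG <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
  E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
  M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
  Y = 0.032, V = 0.073
)

ENERGY_TERMS <- c("total", "ele", "vdw", "gb", "sa")

GB_MODELS <- c("HCT", "OBC1", "OBC2", "GBn1", "GBn2", "synthetic")

# distance shells for ETOR/EPP: shell 0 is the target itself; the rest are
# half-open (lo, hi] intervals in Angstrom
SHELL_BREAKS <- c(0, 3, 4, 5, 6, Inf)
SHELL_LABELS <- c("self", "0-3", "3-4", "4-5", "5-6", "gt6")

ENERGY_GROUPS <- c("EWC", "ETOR", "EPP", "EINI", "EPI")

NONENERGY_GROUPS <- c(
  "bASA", "uASA", "dASA", "bRSA", "uRSA", "dRSA", "IR-dASA", "IR-dRSA",
  "NHB", "IR-NHB", "CFAA", "CFNA", "IR-CFAA", "IR-CFNA",
  "ENDES", "IR-ENDES", "JSD"
)

ALL_GROUPS <- c(ENERGY_GROUPS, NONENERGY_GROUPS)

SASA_CATEGORIES <- c("total", "mainchain", "sidechain",
                     "polar_sidechain", "nonpolar_sidechain")

`%||%` <- function(a, b) if (is.null(a)) b else a
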