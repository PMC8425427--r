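# Fixed lookup tables shared across modules.

#' Standard amino-acid alphabet (one-letter, alphabetical by letter)
#'
#' The canonical 20-letter alphabet used for PSSM columns and the coupling
#' engine's state space. Gap is handled separately as `"-"`.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# three-letter -> one-letter residue codes
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "C", PYL = "K"
)

aa_three_to_one <- function(x) {
  out <- AA_321[toupper(x)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa_one_to_three <- function(x) {
  tbl <- setNames(names(AA_321)[1:20], AA_321[1:20])
  out <- tbl[toupper(x)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

#' Wimley-White whole-residue hydrophobicity scale
#'
#' Free energies of transfer (kcal/mol) from water to the POPC interface for
#' whole residues; the third hydrophobicity channel of the 1D feature block.
#' Unknown residue types map to 0 with a warning at lookup time.
#'
#' @return Named numeric vector over the 20 amino acids.
#' @export
wimley_white_scale <- function() {
  c(A = 0.17, R = 0.81, N = 0.42, D = 1.23, C = -0.24,
    Q = 0.58, E = 2.02, G = 0.01, H = 0.96, I = -0.31,
    K = 0.99, L = -0.56, M = -0.23, F = -1.13, P = 0.45,
    S = 0.13, T = 0.14, W = -1.85, Y = -0.94, V = 0.07)
}

# Chothia-style van der Waals radii by element; unknown elements fall back
# to 1.8 A.
VDW_RADII <- c(C = 1.76, N = 1.65, O = 1.40, S = 1.85, P = 1.90, SE = 1.90)
VDW_DEFAULT <- 1.8

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

# Robinson-Robinson background amino-acid frequencies, used for PSSM log-odds
# and as the sampling background of synthetic alignments.
aa_background <- function() {
  bg <- c(A = 0.0780, C = 0.0192, D = 0.0536, E = 0.0629, F = 0.0386,
          G = 0.0738, H = 0.0219, I = 0.0514, K = 0.0595, L = 0.0901,
          M = 0.0224, N = 0.0448, P = 0.0520, Q = 0.0426, R = 0.0512,
          S = 0.0712, T = 0.0584, V = 0.0644, W = 0.0132, Y = 0.0321)
  bg[aa_alphabet()] / sum(bg)
}

# 8-state secondary-structure alphabet in the fixed one-hot order.
SS8_ALPHABET <- c("H", "B", "E", "G", "I", "T", "S", "-")
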