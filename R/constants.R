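# Monoisotopic element masses (CODATA-derived). Every residue and modification
# mass in the package is computed from atomic composition via this table --
# nothing downstream hard-codes a peptide- or modification-level mass.
ELEMENT_MASS <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

# Mass of a proton (charge carrier for positive-mode m/z).
PROTON_MASS <- 1.00727646688

# Residue (i.e. water-free) atomic compositions of the 20 canonical amino acids.
AA_COMPOSITION <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

mass_from_composition <- function(comp) {
  sum(ELEMENT_MASS[names(comp)] * comp)
}

RESIDUE_MASS <- vapply(AA_COMPOSITION, mass_from_composition, numeric(1))
WATER_MASS <- mass_from_composition(c(H = 2, O = 1))

# Modification atomic compositions:
#   KGG  - di-glycine remnant left on a ubiquitinated lysine after trypsin
#          (two glycine residues, C4H6N2O2)
#   CAM  - carbamidomethylation of cysteine (fixed)
#   OxM  - oxidation of methionine
#   NtAc - protein N-terminal acetylation
MOD_COMPOSITION <- list(
  KGG  = c(C = 4, H = 6, N = 2, O = 2),
  CAM  = c(C = 2, H = 3, N = 1, O = 1),
  OxM  = c(O = 1),
  NtAc = c(C = 2, H = 2, O = 1)
)

MOD_DELTA <- vapply(MOD_COMPOSITION, mass_from_composition, numeric(1))

# Residue each variable modification may sit on ("nterm" = peptide position 1
# of a protein N-terminal peptide).
MOD_TARGET <- c(KGG = "K", OxM = "M", NtAc = "nterm")

#' Monoisotopic residue masses
#'
#' Water-free monoisotopic masses of the 20 canonical amino-acid residues,
#' computed from atomic composition.
#'
#' @return Named numeric vector of residue masses in Da.
#' @export
residue_masses <- function() RESIDUE_MASS

#' Monoisotopic modification deltas
#'
#' Mass shifts of the supported modifications, computed from atomic
#' composition: `KGG` (di-glycine ubiquitin remnant), `CAM`
#' (carbamidomethyl-cysteine, fixed), `OxM` (methionine oxidation) and
#' `NtAc` (protein N-terminal acetylation).
#'
#' @return Named numeric vector of mass deltas in Da.
#' @export
modification_deltas <- function() MOD_DELTA
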