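# Physical constants and residue tables used throughout the pipeline.
# All masses are monoisotopic, in Da.

PROTON_MASS <- 1.007276466
WATER_MASS <- 18.0105646863
# Spacing between successive isotopologues of a natural (C-dominated) envelope:
# m(13C) - m(12C).
ISOTOPE_SPACING <- 1.00335
# Mass added per incorporated deuteron: m(2H) - m(1H).
DEUTERIUM_SHIFT <- 1.006277

# Averagine unit composition (average amino-acid residue) and its mass.
AVERAGINE_UNIT <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
AVERAGINE_UNIT_MASS <- 111.1254

# Monoisotopic element masses.
ELEMENT_MASS <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, S = 31.97207069)

# Per-element natural isotope abundance vectors, indexed by added nominal mass
# (position 1 = lightest isotope, +0).
ISOTOPE_ABUNDANCE <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

# Monoisotopic residue masses (peptide bond already formed; add water for a
# whole peptide).
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Residue elemental compositions (C, H, N, O, S), peptide-bond form.
RESIDUE_COMPOSITION <- rbind(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)
colnames(RESIDUE_COMPOSITION) <- c("C", "H", "N", "O", "S")

AMINO_ACIDS <- names(RESIDUE_MASS)

# Vertebrate background amino-acid frequencies (percent), used by the
# synthetic protein generator.
AA_FREQUENCY <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93, E = 6.75,
  G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
  P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
)

#' Monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water, plus any modification
#' mass deltas falling inside the peptide.
#'
#' @param sequence Amino-acid string (1-letter codes).
#' @param mod_delta Total modification mass delta (Da) to add, default 0.
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mono_mass <- function(sequence, mod_delta = 0) {
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(res, AMINO_ACIDS)
  if (length(bad) > 0) {
    abort(paste0("unknown residue(s): ", paste(unique(bad), collapse = ", ")))
  }
  sum(RESIDUE_MASS[res]) + WATER_MASS + mod_delta
}

#' Elemental composition of a peptide
#'
#' @param sequence Amino-acid string.
#' @return Named numeric vector with counts of C, H, N, O, S (water included).
#' @export
peptide_composition <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(res, AMINO_ACIDS)
  if (length(bad) > 0) {
    abort(paste0("unknown residue(s): ", paste(unique(bad), collapse = ", ")))
  }
  comp <- colSums(RESIDUE_COMPOSITION[res, , drop = FALSE])
  comp["H"] <- comp["H"] + 2
  comp["O"] <- comp["O"] + 1
  comp
}

#' Convert neutral mass to m/z
#'
#' @param mass Neutral mass (Da).
#' @param charge Positive integer charge.
#' @return m/z in Th.
#' @export
mass_to_mz <- function(mass, charge) (mass + charge * PROTON_MASS) / charge

#' Convert m/z to neutral mass
#'
#' @param mz m/z (Th).
#' @param charge Positive integer charge.
#' @return Neutral mass in Da.
#' @export
mz_to_mass <- function(mz, charge) mz * charge - charge * PROTON_MASS
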