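#' Averagine elemental composition for a neutral mass
#'
#' Scales the Averagine average-residue composition
#' (C4.9384 H7.7583 N1.3577 O1.4773 S0.0417 per 111.1254 Da) to the target
#' mass. With `round_composition = TRUE` (the default) the scaled formula is
#' rounded to an integer composition: C, N, O and S are rounded to the
#' nearest integer and the hydrogen count is then chosen so the composition's
#' monoisotopic mass is as close as possible to the target, which keeps the
#' leading isotope ratios close to those of real peptides of that mass.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da), > 0.
#' @param round_composition Round to an integer formula (see above)?
#' @return Named numeric vector of C, H, N, O, S counts.
#' @export
averagine_composition <- function(neutral_mass, round_composition = TRUE) {
  if (!is.numeric(neutral_mass) || neutral_mass <= 0) {
    abort("neutral_mass must be a positive number")
  }
  comp <- AVERAGINE_UNIT * neutral_mass / AVERAGINE_UNIT_MASS
  if (!round_composition) return(comp)
  out <- comp
  for (el in c("C", "N", "O", "S")) out[el] <- round(comp[el])
  heavy <- sum(out[c("C", "N", "O", "S")] * ELEMENT_MASS[c("C", "N", "O", "S")])
  out["H"] <- max(0, round((neutral_mass - heavy) / ELEMENT_MASS["H"]))
  out
}

# Aggregated isotopologue distribution of n atoms of one element, by repeated
# self-convolution (exponentiation by squaring) of the single-atom abundance
# vector, truncated at trunc_tol relative abundance.
element_isotope_dist <- function(abund, n, trunc_tol = 1e-12) {
  result <- 1
  base <- abund / sum(abund)
  n <- as.integer(round(n))
  while (n > 0) {
    if (n %% 2L == 1L) result <- conv_trunc(result, base, trunc_tol)
    n <- n %/% 2L
    if (n > 0) base <- conv_trunc(base, base, trunc_tol)
  }
  result
}

conv_trunc <- function(a, b, tol) {
  out <- stats::convolve(a, rev(b), type = "open")
  out[out < 0] <- 0
  keep <- which(out > tol * max(out))
  out[seq_len(max(keep))]
}

#' Theoretical aggregated isotope pattern
#'
#' Computes unit-mass-binned isotopologue intensities for an elemental
#' composition by convolving per-element natural-abundance vectors, and
#' places them on an m/z grid for the given charge. Fractional counts are
#' rounded to the nearest integer.
#'
#' @param comp Named vector of C, H, N, O, S counts (e.g. from
#'   [averagine_composition()] or [peptide_composition()]).
#' @param charge Positive integer charge.
#' @param min_rel_intensity Truncate trailing isotopes below this fraction of
#'   the maximum (default 1e-3).
#' @param mono_mz Optional monoisotopic m/z; computed from `comp` if missing.
#' @return List of class `isotope_pattern` with elements `mono_mz`, `charge`,
#'   `intensities` (max normalized to 1), `spacing` (Th per isotope index).
#' @export
isotope_pattern <- function(comp, charge = 1L, min_rel_intensity = 1e-3,
                            mono_mz = NULL) {
  if (charge < 1) abort("charge must be >= 1")
  comp <- comp[intersect(names(ISOTOPE_ABUNDANCE), names(comp))]
  dist <- 1
  for (el in names(comp)) {
    if (comp[[el]] >= 0.5) {
      dist <- conv_trunc(dist, element_isotope_dist(ISOTOPE_ABUNDANCE[[el]], comp[[el]]),
                         1e-12)
    }
  }
  dist <- dist / max(dist)
  keep <- which(dist >= min_rel_intensity)
  dist <- dist[seq_len(max(keep))]
  if (is.null(mono_mz)) {
    mono_mz <- mass_to_mz(sum(ELEMENT_MASS[names(comp)] * unlist(comp)), charge)
  }
  structure(list(mono_mz = mono_mz, charge = as.integer(charge),
                 intensities = dist, spacing = ISOTOPE_SPACING / charge),
            class = "isotope_pattern")
}

#' Averagine isotope pattern for a neutral mass
#'
#' Convenience wrapper: Averagine composition, then [isotope_pattern()], with
#' the monoisotopic m/z fixed at the requested mass (not the rounded
#' formula's).
#'
#' @inheritParams averagine_composition
#' @inheritParams isotope_pattern
#' @return An `isotope_pattern`.
#' @export
averagine_pattern <- function(neutral_mass, charge = 1L, min_rel_intensity = 1e-3) {
  comp <- averagine_composition(neutral_mass)
  isotope_pattern(comp, charge, min_rel_intensity,
                  mono_mz = mass_to_mz(neutral_mass, charge))
}

#' Number of exchangeable backbone amides
#'
#' Residues minus one (the N-terminal amine is not a backbone amide) minus
#' prolines at positions 2..length, which have no amide hydrogen.
#'
#' @param sequence Amino-acid string.
#' @return Integer count (0 for sequences shorter than 2 residues).
#' @export
count_exchangeable_amides <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  if (length(res) < 2) return(0L)
  as.integer(length(res) - 1L - sum(res[-1] == "P"))
}

#' In-silico deuterated isotope pattern
#'
#' Forward model of deuteration: the natural isotope envelope is convolved
#' with a deuteration-state distribution; peak j sits at
#' `mono_mz + j * 1.006277 / charge`.
#'
#' @param natural An `isotope_pattern` (natural envelope).
#' @param dist Numeric vector of normalized deuteration-state weights
#'   (index 1 = 0 deuterons), or a `deut_dist` object.
#' @return An `isotope_pattern` with `spacing` set to the deuterium shift per
#'   charge and intensities renormalized to max 1.
#' @export
deuterated_pattern <- function(natural, dist) {
  if (inherits(dist, "deut_dist")) dist <- dist$weights
  if (any(dist < 0)) abort("distribution weights must be non-negative")
  dist <- dist / sum(dist)
  nat <- natural$intensities
  out <- numeric(length(nat) + length(dist) - 1L)
  for (k in seq_along(dist)) {
    idx <- seq_along(nat) + k - 1L
    out[idx] <- out[idx] + dist[k] * nat
  }
  structure(list(mono_mz = natural$mono_mz, charge = natural$charge,
                 intensities = out / max(out),
                 spacing = DEUTERIUM_SHIFT / natural$charge),
            class = "isotope_pattern")
}

#' Predicted m/z grid after deuteration
#'
#' All m/z positions at which signal of a (partially) deuterated peptide can
#' appear: combinations of k incorporated deuterons (k = 0..n_exchangeable,
#' spacing 1.006277/z) and i natural heavy isotopes (i = 0..max_isotopes,
#' spacing 1.00335/z). Positions are grouped by total isotope index
#' j = k + i; near-duplicates (within 1e-6 Th) are dropped.
#'
#' @param mono_mz Monoisotopic m/z of the undeuterated species (Th).
#' @param charge Positive integer charge.
#' @param n_exchangeable Number of exchangeable amides (>= 0).
#' @param max_isotopes Natural isotopes to include beyond the deuteration
#'   states (default 2).
#' @return Tibble with columns `index` (total isotope index j) and `mz`,
#'   sorted by mz.
#' @export
predicted_deuterated_mz <- function(mono_mz, charge, n_exchangeable,
                                    max_isotopes = 2L) {
  if (n_exchangeable < 0) abort("n_exchangeable must be >= 0")
  grid <- tidyr::expand_grid(k = 0:n_exchangeable, i = 0:max_isotopes)
  grid$index <- grid$k + grid$i
  grid$mz <- mono_mz + (grid$k * DEUTERIUM_SHIFT + grid$i * ISOTOPE_SPACING) / charge
  grid <- arrange(grid[, c("index", "mz")], .data$mz)
  keep <- c(TRUE, diff(grid$mz) > 1e-6)
  grid[keep, ]
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat(sprintf("<isotope_pattern> mono m/z %.4f, z=%d, %d isotopes, spacing %.5f Th\n",
              x$mono_mz, x$charge, length(x$intensities), x$spacing))
  invisible(x)
}
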