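#' Default deconvolution / extraction parameters
#'
#' @param iterations Gold iteration budget (default 10000, with early stop at
#'   relative change < 1e-8).
#' @param boost_every Apply boosting every this many iterations (default 50).
#' @param boost_exponent Boosting exponent (default 1.2).
#' @param boost_iterations Boosting is confined to this initial stretch of
#'   iterations (default 500, i.e. ten boost applications); plain Gold
#'   iterations then run to convergence. Perpetual boosting would bias smooth
#'   solutions away from the exact inverse.
#' @param min_consecutive Consecutive isotopes with appreciable intensity
#'   required to accept an envelope (default 3).
#' @param intensity_floor_fraction "Appreciable" = at least this fraction of
#'   the envelope maximum (default 0.05).
#' @param min_total Minimum summed envelope intensity (counts).
#' @param box_ppm m/z box half-width for intensity extraction (ppm).
#' @param max_isotopes Natural isotopes added beyond the deuteration states.
#' @return Named list.
#' @export
deut_params <- function(iterations = 10000L, boost_every = 50L,
                        boost_exponent = 1.2, boost_iterations = 500L,
                        min_consecutive = 3L,
                        intensity_floor_fraction = 0.05, min_total = 0,
                        box_ppm = 4, max_isotopes = 2L) {
  list(iterations = iterations, boost_every = boost_every,
       boost_exponent = boost_exponent, boost_iterations = boost_iterations,
       min_consecutive = min_consecutive,
       intensity_floor_fraction = intensity_floor_fraction,
       min_total = min_total, box_ppm = box_ppm, max_isotopes = max_isotopes)
}

#' Extract a deuterated isotope envelope
#'
#' Sums, over all scans inside the mapped elution window, the intensity of
#' the nearest peak within the ppm box at each predicted deuterated m/z
#' position (grouped by total isotope index). The envelope is rejected when
#' fewer than `min_consecutive` consecutive indices carry appreciable
#' intensity or the total intensity is below the floor.
#'
#' @param map Deuterated `lcms_map`.
#' @param feature One feature row (mono_mass, charge, rt_start, rt_end).
#' @param mapping `rt_mapping` with tolerance filled (or NULL for identity).
#' @param n_states Number of deuteration states N (exchangeable amides).
#' @param params [deut_params()].
#' @return List of class `observed_envelope` with `intensities` (index 0
#'   upward), `mono_mz`, `charge`, `n_consecutive`, `rt_window`; or a list of
#'   class `envelope_rejection` with a `reason`.
#' @export
extract_envelope <- function(map, feature, mapping = NULL, n_states,
                             params = deut_params()) {
  sc <- map_scans(map)
  if (is.null(mapping)) {
    win <- c(feature$rt_start, feature$rt_end)
  } else {
    lo <- predict(mapping, feature$rt_start - mapping$peak_width_extension)
    hi <- predict(mapping, feature$rt_end + mapping$peak_width_extension)
    tol <- local_tolerance(mapping, c(feature$rt_start, feature$rt_end))
    win <- c(lo - tol[1], hi + tol[2])
  }
  scans_in <- sc$scan[sc$rt >= win[1] & sc$rt <= win[2]]
  if (length(scans_in) == 0) {
    return(structure(list(reason = "window outside map"),
                     class = "envelope_rejection"))
  }
  mono_mz <- mass_to_mz(feature$mono_mass, feature$charge)
  # enough natural isotopes beyond the deuteration states to cover the full
  # envelope of heavy peptides (the natural envelope lengthens with mass)
  n_iso <- max(params$max_isotopes, ceiling(2 + feature$mono_mass / 400))
  grid <- predicted_deuterated_mz(mono_mz, feature$charge, n_states, n_iso)
  n_idx <- max(grid$index) + 1L
  tb <- as_tibble(map)
  tb <- tb[tb$scan %in% scans_in, ]
  per_scan <- matrix(0, length(scans_in), n_idx)
  for (si in seq_along(scans_in)) {
    s <- scans_in[si]
    mz_obs <- tb$mz[tb$scan == s]
    if (length(mz_obs) == 0) next
    int_obs <- tb$intensity[tb$scan == s]
    idx <- findInterval(grid$mz, mz_obs)
    lo_i <- pmax(idx, 1L); hi_i <- pmin(idx + 1L, length(mz_obs))
    use_hi <- abs(mz_obs[hi_i] - grid$mz) < abs(mz_obs[lo_i] - grid$mz)
    near <- ifelse(use_hi, hi_i, lo_i)
    ok <- abs(mz_obs[near] - grid$mz) / grid$mz * 1e6 <= params$box_ppm
    if (!any(ok)) next
    # best (nearest) match per isotope index in this scan
    hits <- tibble(index = grid$index[ok], peak = near[ok],
                   d = abs(mz_obs[near[ok]] - grid$mz[ok]))
    hits <- hits %>% group_by(.data$index) %>%
      slice(which.min(.data$d)) %>% ungroup()
    per_scan[si, hits$index + 1L] <- int_obs[hits$peak]
  }
  # integrate only over the contiguous elution core around the apex scan, so
  # tolerance slack in the search window does not accumulate baseline noise
  totals <- rowSums(per_scan)
  if (any(totals > 0)) {
    apex <- which.max(totals)
    core <- totals >= 0.1 * totals[apex]
    lo_c <- apex; while (lo_c > 1 && core[lo_c - 1]) lo_c <- lo_c - 1
    hi_c <- apex; while (hi_c < length(core) && core[hi_c + 1]) hi_c <- hi_c + 1
    sums <- colSums(per_scan[lo_c:hi_c, , drop = FALSE])
  } else {
    sums <- numeric(n_idx)
  }
  if (sum(sums) <= params$min_total || all(sums == 0)) {
    return(structure(list(reason = "below intensity floor"),
                     class = "envelope_rejection"))
  }
  # acceptance requires a run of consecutive isotope indices with signal;
  # counted on the raw sums, since near-threshold isotopes of weak peptides
  # are real signal even when below the "appreciable" floor
  runs_nz <- rle(sums > 0)
  if (max(c(0L, runs_nz$lengths[runs_nz$values])) < params$min_consecutive) {
    return(structure(list(reason = "too few isotopes"),
                     class = "envelope_rejection"))
  }
  # n_consecutive reports the stricter appreciable-intensity run
  appreciable <- sums >= params$intensity_floor_fraction * max(sums)
  runs <- rle(appreciable)
  n_consec <- max(c(0L, runs$lengths[runs$values]))
  # zero sub-floor indices for the deconvolution input: they carry mostly
  # noise and would bias the deconvolved centroid
  sums[!appreciable] <- 0
  structure(list(intensities = sums, mono_mz = mono_mz,
                 charge = feature$charge, n_consecutive = as.integer(n_consec),
                 rt_window = win),
            class = "observed_envelope")
}

#' Boosted Gold deconvolution of a deuteration distribution
#'
#' Solves `y = A d`, `d >= 0`, where column k of A is the natural isotope
#' pattern shifted by k deuteration states, using Gold's multiplicative
#' iteration `d_i <- d_i (A'y)_i / (A'A d)_i` from a uniform positive start.
#' During the initial `boost_iterations`, the estimate is sharpened every
#' `boost_every` iterations by `d_i <- d_i^boost_exponent` and renormalized;
#' plain iterations then run to convergence. `A'A` and `A'y` are precomputed
#' once. The scheme keeps coefficients positive and favors smooth solutions.
#'
#' @param observed An `observed_envelope` or a bare non-negative numeric
#'   vector of envelope intensities (index 0 upward).
#' @param natural Natural `isotope_pattern` of the peptide (point spread
#'   function).
#' @param n_states Number of deuteration states N (weights run 0..N).
#' @param params [deut_params()].
#' @return Object of class `deut_dist`: `weights` (length N+1, normalized),
#'   `centroid` (deuterons), `centroid_da`, `iterations`, `converged`.
#' @export
gold_deconvolve <- function(observed, natural, n_states,
                            params = deut_params()) {
  y <- if (inherits(observed, "observed_envelope")) observed$intensities else observed
  y <- pmax(as.numeric(y), 0)
  if (all(y == 0)) abort("all-zero observed envelope")
  psf <- natural$intensities / sum(natural$intensities)
  m <- length(psf)
  n_rows <- max(length(y), n_states + m)
  y <- c(y, numeric(n_rows - length(y)))
  A <- matrix(0, n_rows, n_states + 1L)
  for (k in 0:n_states) A[k + seq_len(m), k + 1L] <- psf
  AtA <- crossprod(A)
  Aty <- drop(crossprod(A, y))
  d <- rep(1 / (n_states + 1), n_states + 1L)
  converged <- FALSE
  it <- 0L
  while (it < params$iterations) {
    it <- it + 1L
    denom <- drop(AtA %*% d)
    ratio <- ifelse(denom > 0, Aty / denom, 0)
    d_new <- d * ratio
    if (it <= params$boost_iterations && it %% params$boost_every == 0L) {
      d_new <- d_new^params$boost_exponent
      s <- sum(d_new)
      if (s > 0) d_new <- d_new / s * sum(d)
    }
    delta <- sum(abs(d_new - d)) / max(sum(d), 1e-300)
    d <- d_new
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  if (sum(d) == 0) abort("deconvolution collapsed to zero")
  w <- d / sum(d)
  new_deut_dist(w, iterations = it, converged = converged)
}

new_deut_dist <- function(weights, iterations = NA_integer_, converged = NA) {
  cen <- sum((seq_along(weights) - 1) * weights)
  structure(list(weights = weights, n_states = length(weights) - 1L,
                 centroid = cen, centroid_da = cen * DEUTERIUM_SHIFT,
                 iterations = iterations, converged = converged),
            class = "deut_dist")
}

#' Deuteration-distribution centroid
#'
#' Intensity-weighted mean deuteration state of a normalized distribution,
#' in deuterons and in Da (x 1.006277).
#'
#' @param dist A `deut_dist` or bare weight vector (index 0 upward).
#' @return Named numeric vector `c(deuterons = ..., da = ...)`.
#' @export
deuteration_centroid <- function(dist) {
  w <- if (inherits(dist, "deut_dist")) dist$weights else dist / sum(dist)
  cen <- sum((seq_along(w) - 1) * w)
  c(deuterons = cen, da = cen * DEUTERIUM_SHIFT)
}

#' Back-exchange correction of a deuteration centroid
#'
#' Ratio correction against a fully deuterated control:
#' `D_corrected = N * centroid_da / centroid_da_full` (the undeuterated
#' centroid is zero by construction of the deconvolved distribution). With
#' no control the relative value `centroid_da / (N * 1.006277)` is returned
#' and flagged uncorrected; such values still support comparative
#' experiments under identical LC-MS conditions.
#'
#' @param centroid_da Observed centroid (Da).
#' @param centroid_da_full Centroid of the 100% control (Da), or NA.
#' @param n_exchangeable Exchangeable amides N.
#' @return List: `deuterons` (corrected count, or relative fraction when
#'   uncorrected), `corrected` (logical), `flagged` (TRUE when the observed
#'   value exceeds the control).
#' @export
back_exchange_correct <- function(centroid_da, centroid_da_full, n_exchangeable) {
  if (is.na(centroid_da_full) || is.null(centroid_da_full)) {
    return(list(deuterons = centroid_da / (n_exchangeable * DEUTERIUM_SHIFT),
                corrected = FALSE, flagged = FALSE))
  }
  if (centroid_da_full <= 0) abort("control centroid must be positive")
  flagged <- centroid_da > centroid_da_full
  if (flagged) warn("observed centroid exceeds the fully deuterated control")
  list(deuterons = n_exchangeable * centroid_da / centroid_da_full,
       corrected = TRUE, flagged = flagged)
}

#' @export
print.deut_dist <- function(x, ...) {
  cat(sprintf("<deut_dist> %d states, centroid %.2f D (%.3f Da)%s\n",
              x$n_states + 1L, x$centroid, x$centroid_da,
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}
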