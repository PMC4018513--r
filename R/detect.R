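#' Default feature-detection parameters
#'
#' @param snr_threshold Minimum peak signal-to-noise for candidate seeding.
#' @param charge_min,charge_max Charge states considered.
#' @param sample_tol_ppm Tolerance for sampling theoretical isotope peaks
#'   onto observed line positions.
#' @param min_gap m/z gap (Th) above which a scan is split into segments;
#'   default 1.5/charge_min, larger than any within-envelope spacing at the
#'   lowest charge.
#' @param max_envelope_width Soft cap on segment width (Th); wide segments
#'   are split at their largest internal gap.
#' @param mono_hypotheses Isotope indices a seed peak may occupy in its
#'   envelope (default 0:2; the monoisotopic peak can be weak for heavy
#'   peptides).
#' @param mass_range Admissible neutral masses (Da) for candidates.
#' @param min_scans Minimum scans per eluting feature.
#' @param max_internal_gaps Missing scans tolerated inside an elution chain.
#' @param mass_tol_ppm Mass tolerance for chaining detections across scans.
#' @param candidate_min_rel Isotope-pattern truncation for candidates.
#' @return Named list of parameters.
#' @export
detect_params <- function(snr_threshold = 3, charge_min = 1L, charge_max = 6L,
                          sample_tol_ppm = 10, min_gap = NULL,
                          max_envelope_width = 40,
                          mono_hypotheses = 0:2,
                          mass_range = c(200, 8000),
                          min_scans = 2L, max_internal_gaps = 1L,
                          mass_tol_ppm = 10, candidate_min_rel = 0.01) {
  if (is.null(min_gap)) min_gap <- 1.5 / charge_min
  list(snr_threshold = snr_threshold, charge_min = charge_min,
       charge_max = charge_max, sample_tol_ppm = sample_tol_ppm,
       min_gap = min_gap, max_envelope_width = max_envelope_width,
       mono_hypotheses = mono_hypotheses, mass_range = mass_range,
       min_scans = min_scans, max_internal_gaps = max_internal_gaps,
       mass_tol_ppm = mass_tol_ppm, candidate_min_rel = candidate_min_rel)
}

#' Split a scan into segments of non-overlapping envelopes
#'
#' Contiguous runs of peaks are split wherever the m/z gap between adjacent
#' peaks exceeds `min_gap`; segments wider than `max_envelope_width` are
#' further split at their largest internal gap. Segments are disjoint and
#' cover all peaks.
#'
#' @param peaks Tibble of one scan's peaks, sorted by mz.
#' @param min_gap Gap threshold (Th).
#' @param max_envelope_width Soft width cap (Th); `Inf` disables.
#' @return Integer vector of segment ids, one per peak.
#' @export
segment_scan <- function(peaks, min_gap = 1.5, max_envelope_width = Inf) {
  n <- nrow(peaks)
  if (n == 0) return(integer(0))
  gaps <- diff(peaks$mz)
  seg <- cumsum(c(1L, as.integer(gaps > min_gap)))
  if (is.finite(max_envelope_width)) {
    repeat {
      widths <- tapply(peaks$mz, seg, function(z) diff(range(z)))
      wide <- names(widths)[widths > max_envelope_width]
      if (length(wide) == 0) break
      changed <- FALSE
      for (w in wide) {
        idx <- which(seg == as.integer(w))
        if (length(idx) < 2) next
        g <- diff(peaks$mz[idx])
        cut <- which.max(g)
        if (g[cut] <= 0) next
        seg[idx[(cut + 1):length(idx)]] <- max(seg) + 1L
        changed <- TRUE
      }
      if (!changed) break
    }
    seg <- as.integer(factor(seg, levels = unique(seg)))
  }
  seg
}

# Robust per-scan noise level: 1.4826 * median absolute intensity, floored at
# one count.
estimate_noise <- function(intensities) {
  max(1, 1.4826 * median(abs(intensities)))
}

#' Generate candidate isotope patterns for a segment
#'
#' Every peak at or above the SNR threshold seeds one Averagine pattern per
#' charge state and per hypothesis about which isotope index (0, 1 or 2) the
#' peak occupies. Duplicates (same charge, monoisotopic m/z within the merge
#' tolerance) are removed.
#'
#' @param peaks Segment peaks (tibble with mz, intensity).
#' @param noise Noise level of the scan (counts).
#' @param params [detect_params()] list.
#' @return List of `isotope_pattern` candidates (possibly empty).
#' @export
generate_candidates <- function(peaks, noise, params = detect_params()) {
  if (nrow(peaks) == 0) return(list())
  seeds <- peaks$mz[peaks$intensity / noise >= params$snr_threshold]
  if (length(seeds) == 0) return(list())
  # charge states must be consistent with an observed adjacent-peak spacing:
  # for each seed keep charges z with a neighbouring peak at ~1.00335/z on
  # either side; isolated seeds admit every charge
  zs <- params$charge_min:params$charge_max
  combos <- purrr::map_dfr(seeds, function(mz0) {
    tol <- pmax(2 * params$sample_tol_ppm * mz0 * 1e-6, 0.005)
    ok <- vapply(zs, function(z) {
      sp <- ISOTOPE_SPACING / z
      any(abs(peaks$mz - (mz0 + sp)) <= tol) || any(abs(peaks$mz - (mz0 - sp)) <= tol)
    }, logical(1))
    if (!any(ok)) ok[] <- TRUE
    tidyr::expand_grid(mz0 = mz0, z = zs[ok], h = params$mono_hypotheses)
  })
  combos$mono_mz <- combos$mz0 - combos$h * ISOTOPE_SPACING / combos$z
  combos$mass <- mz_to_mass(combos$mono_mz, combos$z)
  combos <- combos[combos$mass >= params$mass_range[1] &
                     combos$mass <= params$mass_range[2], ]
  if (nrow(combos) == 0) return(list())
  # dedupe within mass_tol_ppm per charge
  combos <- arrange(combos, .data$z, .data$mono_mz)
  keep <- rep(TRUE, nrow(combos))
  last_mz <- -Inf; last_z <- -1L
  for (i in seq_len(nrow(combos))) {
    if (combos$z[i] == last_z &&
        (combos$mono_mz[i] - last_mz) / last_mz * 1e6 < params$mass_tol_ppm) {
      keep[i] <- FALSE
    } else {
      last_mz <- combos$mono_mz[i]; last_z <- combos$z[i]
    }
  }
  combos <- combos[keep, ]
  purrr::pmap(list(combos$mass, combos$z, combos$mono_mz),
              function(m, z, mzm) {
                p <- averagine_pattern(m, z, params$candidate_min_rel)
                p$mono_mz <- mzm
                p
              })
}

# Sample candidate patterns onto observed peak positions: theoretical peak
# intensities are assigned to the nearest observed peak within sample_tol_ppm.
# A substantial theoretical peak (rel >= miss_min_rel) with no observed match
# becomes a pseudo-observation of intensity zero, so candidates that predict
# signal where the spectrum shows none are penalized rather than silently
# truncated. Returns the design matrix and the number of zero rows appended.
sample_candidates <- function(candidates, mz_obs, sample_tol_ppm,
                              miss_min_rel = 0.1) {
  n <- length(mz_obs)
  cols <- vector("list", length(candidates))
  miss <- vector("list", length(candidates))
  for (j in seq_along(candidates)) {
    p <- candidates[[j]]
    theo_mz <- p$mono_mz + (seq_along(p$intensities) - 1L) * p$spacing
    col <- numeric(n)
    missed <- numeric(0)
    idx <- findInterval(theo_mz, mz_obs)
    for (t in seq_along(theo_mz)) {
      lo <- max(1, idx[t]); hi <- min(n, idx[t] + 1L)
      d <- abs(mz_obs[lo:hi] - theo_mz[t])
      best <- lo + which.min(d) - 1L
      if (abs(mz_obs[best] - theo_mz[t]) / theo_mz[t] * 1e6 <= sample_tol_ppm) {
        col[best] <- col[best] + p$intensities[t]
      } else if (p$intensities[t] >= miss_min_rel) {
        missed <- c(missed, p$intensities[t])
      }
    }
    cols[[j]] <- col
    miss[[j]] <- missed
  }
  n_miss <- sum(lengths(miss))
  Phi <- matrix(0, n + n_miss, length(candidates))
  for (j in seq_along(cols)) Phi[seq_len(n), j] <- cols[[j]]
  row <- n
  for (j in seq_along(miss)) {
    for (v in miss[[j]]) {
      row <- row + 1L
      Phi[row, j] <- v
    }
  }
  list(Phi = Phi, n_miss = n_miss)
}

#' Detect features in one scan
#'
#' Segments the scan, generates Averagine candidates per segment, solves the
#' non-negative LARS path and keeps the BIC-optimal support.
#'
#' @param peaks One scan's peaks (tibble with mz, intensity), sorted by mz.
#' @param params [detect_params()].
#' @return Tibble with columns mono_mass, charge, beta (one row per detected
#'   species in this scan).
#' @export
detect_features_scan <- function(peaks, params = detect_params()) {
  out <- list()
  if (nrow(peaks) == 0) {
    return(tibble(mono_mass = double(), charge = integer(), beta = double()))
  }
  noise <- estimate_noise(peaks$intensity)
  seg <- segment_scan(peaks, params$min_gap, params$max_envelope_width)
  for (sid in unique(seg)) {
    sp <- peaks[seg == sid, , drop = FALSE]
    cands <- generate_candidates(sp, noise, params)
    if (length(cands) == 0) next
    smp <- sample_candidates(cands, sp$mz, params$sample_tol_ppm)
    Phi <- smp$Phi
    obs_rows <- seq_len(nrow(sp))
    nz <- colSums(Phi[obs_rows, , drop = FALSE]) > 0
    cands <- cands[nz]
    Phi <- Phi[, nz, drop = FALSE]
    if (ncol(Phi) == 0) next
    path <- nn_lars(Phi, c(sp$intensity, numeric(smp$n_miss)))
    sol <- select_bic(path, n = nrow(sp))
    hit <- which(sol$beta > 0)
    if (length(hit) == 0) next
    out[[length(out) + 1L]] <- tibble(
      mono_mass = vapply(cands[hit], function(p) mz_to_mass(p$mono_mz, p$charge), 0),
      charge = vapply(cands[hit], function(p) p$charge, 0L),
      beta = sol$beta[hit]
    )
  }
  if (length(out) == 0) {
    return(tibble(mono_mass = double(), charge = integer(), beta = double()))
  }
  bind_rows(out)
}

#' Merge per-scan detections into eluting features
#'
#' Detections of equal charge with monoisotopic masses within tolerance are
#' chained across consecutive scans; a chain tolerates up to
#' `max_internal_gaps` missing scans anywhere inside and must span at least
#' `min_scans` scans.
#'
#' @param detections Tibble with columns scan, rt, mono_mass, charge, beta.
#' @param params [detect_params()].
#' @return Feature tibble: feature, mono_mass, charge, abundance, rt_start,
#'   rt_apex, rt_end, n_scans, trace (list-column of per-scan tibbles).
#' @export
merge_elution_profiles <- function(detections, params = detect_params()) {
  empty <- tibble(feature = integer(), mono_mass = double(), charge = integer(),
                  abundance = double(), rt_start = double(), rt_apex = double(),
                  rt_end = double(), n_scans = integer(), trace = list())
  if (nrow(detections) == 0) return(empty)
  det <- arrange(detections, .data$charge, .data$mono_mass)
  # mass clusters per charge
  new_cluster <- c(TRUE, diff(det$mono_mass) / head(det$mono_mass, -1) * 1e6 >
                     params$mass_tol_ppm | diff(det$charge) != 0)
  det$cluster <- cumsum(new_cluster)
  feats <- list()
  for (cl in unique(det$cluster)) {
    d <- arrange(det[det$cluster == cl, ], .data$scan)
    # split where the scan gap exceeds the allowance
    chain <- cumsum(c(1L, as.integer(diff(d$scan) > params$max_internal_gaps + 1L)))
    for (ch in unique(chain)) {
      dd <- d[chain == ch, ]
      # collapse multiple detections in the same scan
      dd <- dd %>% group_by(.data$scan, .data$rt) %>%
        summarise(mono_mass = weighted.mean(.data$mono_mass, .data$beta),
                  beta = sum(.data$beta), .groups = "drop")
      if (nrow(dd) < params$min_scans) next
      # enforce the total internal-gap budget
      internal_gaps <- sum(pmax(diff(dd$scan) - 1L, 0L))
      if (internal_gaps > params$max_internal_gaps) {
        # cut at the largest gap and re-evaluate both halves via recursion
        cut <- which.max(diff(dd$scan))
        for (half in list(dd[seq_len(cut), ], dd[(cut + 1):nrow(dd), ])) {
          sub <- merge_elution_profiles(
            mutate(half, charge = d$charge[1]), params)
          if (nrow(sub) > 0) feats <- c(feats, list(sub))
        }
        next
      }
      feats[[length(feats) + 1L]] <- tibble(
        mono_mass = weighted.mean(dd$mono_mass, dd$beta),
        charge = d$charge[1],
        abundance = sum(dd$beta),
        rt_start = min(dd$rt), rt_apex = dd$rt[which.max(dd$beta)],
        rt_end = max(dd$rt), n_scans = nrow(dd),
        trace = list(dd[, c("scan", "rt", "beta")])
      )
    }
  }
  if (length(feats) == 0) return(empty)
  out <- bind_rows(feats)
  out <- suppress_satellites(out, params)
  out <- arrange(out, .data$mono_mass, .data$charge)
  mutate(out, feature = row_number(), .before = 1)
}

# Remove isotope-satellite, duplicate and harmonic charge-alias features.
# Same charge: a feature k = 0..3 isotope spacings away in neutral mass from
# a stronger rt-overlapping feature is a chain-split duplicate (k = 0, always
# dropped) or an envelope satellite (k >= 1, dropped when much weaker).
# Different charges: when the lower charge divides the higher one, the lower
# charge's envelope samples a subset of the higher's peaks (e.g. every third
# peak of a 3+ envelope is spaced like a 1+ envelope); the lower-charge
# feature whose monoisotopic m/z sits on the higher-charge envelope grid is
# the alias and is dropped.
suppress_satellites <- function(features, params, satellite_ratio = 0.3,
                                shadow_ratio = 0.3, alias_ratio = 0.1,
                                rt_slack = 15) {
  if (nrow(features) < 2) return(features)
  out <- arrange(features, desc(.data$abundance))
  keep <- rep(TRUE, nrow(out))
  mono_mz <- mass_to_mz(out$mono_mass, out$charge)
  # approximate m/z span of each feature's isotope envelope
  env_hi <- mono_mz + (3 + out$mono_mass / 500) * ISOTOPE_SPACING / out$charge
  n <- nrow(out)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j || !keep[j] || !keep[i]) next
      if (out$rt_start[i] > out$rt_end[j] + rt_slack ||
          out$rt_end[i] < out$rt_start[j] - rt_slack) next
      zi <- out$charge[i]; zj <- out$charge[j]
      stronger_j <- out$abundance[j] >= out$abundance[i]
      if (zi == zj) {
        if (!stronger_j) next  # handled from the other side
        dm <- abs(out$mono_mass[i] - out$mono_mass[j])
        k <- round(dm / ISOTOPE_SPACING)
        tol <- 2 * params$mass_tol_ppm * out$mono_mass[j] * 1e-6
        if (k <= 6 && abs(dm - k * ISOTOPE_SPACING) <= tol &&
            (k == 0 || out$abundance[i] < satellite_ratio * out$abundance[j])) {
          keep[i] <- FALSE
          break
        }
      } else if (zj > zi && zj %% zi == 0 &&
                 out$abundance[j] >= alias_ratio * out$abundance[i]) {
        # harmonic charge alias: i's mono m/z sits on j's envelope grid
        sp_j <- ISOTOPE_SPACING / zj
        r <- (mono_mz[i] - mono_mz[j]) / sp_j
        tolmz <- 2 * params$mass_tol_ppm * mono_mz[j] * 1e-6
        if (round(r) >= 0 && round(r) <= 12 &&
            abs(r - round(r)) * sp_j <= tolmz) {
          keep[i] <- FALSE
          break
        }
      }
      # shadow rule: a much weaker feature living inside a stronger feature's
      # envelope m/z region and elution span is detection debris
      if (keep[i] && stronger_j &&
          out$abundance[i] < shadow_ratio * out$abundance[j] &&
          mono_mz[i] >= mono_mz[j] - 1.1 && mono_mz[i] <= env_hi[j] + 1.1) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out[keep, ]
}

#' Detect eluting features in a reference LC-MS map
#'
#' Runs [detect_features_scan()] on every scan and merges detections into
#' elution profiles.
#'
#' @param map An `lcms_map` (undeuterated reference).
#' @param params [detect_params()].
#' @return Feature tibble (see [merge_elution_profiles()]).
#' @export
detect_features <- function(map, params = detect_params()) {
  sc <- map_scans(map)
  per_scan <- purrr::map_dfr(seq_len(nrow(sc)), function(i) {
    pk <- as_tibble(map)[map$scan == sc$scan[i], ]
    d <- detect_features_scan(pk, params)
    if (nrow(d) == 0) return(d)
    mutate(d, scan = sc$scan[i], rt = sc$rt[i])
  })
  merge_elution_profiles(per_scan, params)
}
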