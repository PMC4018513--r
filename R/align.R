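#' Default alignment parameters
#'
#' @param min_consecutive_isotopes Consecutive predicted isotope indices that
#'   must each match an observed peak for a scan to count as an alignment
#'   candidate (default 3).
#' @param box_ppm Half-width of the m/z match box in ppm (instrument
#'   precision, default 4).
#' @param n_segments Piecewise-linear segments of the retention-time mapping
#'   (default 8).
#' @param tolerance_floor_s Lower bound on the local tolerance half-width
#'   (s), default 10.
#' @param k_tolerance Multiplier on the local residual SD (default 2).
#' @param max_isotopes Natural isotopes added beyond the deuteration states
#'   when predicting deuterated m/z.
#' @param min_candidates Minimum candidates required for a coarse fit.
#' @return Named list.
#' @export
align_params <- function(min_consecutive_isotopes = 3L, box_ppm = 4,
                         n_segments = 8L, tolerance_floor_s = 10,
                         k_tolerance = 2, max_isotopes = 2L,
                         min_candidates = 10L) {
  list(min_consecutive_isotopes = min_consecutive_isotopes, box_ppm = box_ppm,
       n_segments = n_segments, tolerance_floor_s = tolerance_floor_s,
       k_tolerance = k_tolerance, max_isotopes = max_isotopes,
       min_candidates = min_candidates)
}

#' Find retention-time alignment candidates
#'
#' For every target scan and every reference feature, probes all m/z values
#' expected after deuteration ([predicted_deuterated_mz()]) against the
#' scan's peaks within a ppm box (sorted-merge interval search: every
#' box intersection is found, none invented). Scans where at least
#' `min_consecutive_isotopes` consecutive isotope indices match become
#' (rt_ref, rt_target) candidates.
#'
#' @param ref_features Feature tibble; needs mono_mass, charge, rt_apex and
#'   an `n_exchangeable` column (upper bound over candidate sequences; for
#'   unassigned features use `ceiling(mono_mass / 111.1254)`).
#' @param target_map Deuterated `lcms_map`.
#' @param params [align_params()].
#' @return Tibble: feature, rt_ref, rt_target, n_isotopes_matched.
#' @export
find_alignment_candidates <- function(ref_features, target_map,
                                      params = align_params()) {
  empty <- tibble(feature = integer(), rt_ref = double(), rt_target = double(),
                  n_isotopes_matched = integer())
  sc <- map_scans(target_map)
  if (nrow(sc) == 0 || nrow(ref_features) == 0) return(empty)
  feats <- ref_features
  if (!"n_exchangeable" %in% names(feats)) {
    feats$n_exchangeable <- ceiling(feats$mono_mass / AVERAGINE_UNIT_MASS)
  }
  # precompute the probe grid of every feature once
  grids <- purrr::map(seq_len(nrow(feats)), function(i) {
    g <- predicted_deuterated_mz(mass_to_mz(feats$mono_mass[i], feats$charge[i]),
                                 feats$charge[i], feats$n_exchangeable[i],
                                 params$max_isotopes)
    g$feature_row <- i
    g
  })
  probe <- bind_rows(grids)
  tb <- as_tibble(target_map)
  out <- vector("list", nrow(sc))
  for (s in seq_len(nrow(sc))) {
    mz_obs <- tb$mz[tb$scan == sc$scan[s]]
    if (length(mz_obs) == 0) next
    idx <- findInterval(probe$mz, mz_obs)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(mz_obs))
    d_lo <- abs(mz_obs[lo] - probe$mz)
    d_hi <- abs(mz_obs[hi] - probe$mz)
    nearest <- pmin(d_lo, d_hi)
    hitp <- nearest / probe$mz * 1e6 <= params$box_ppm
    if (!any(hitp)) next
    hits <- probe[hitp, c("feature_row", "index")]
    hits <- distinct(hits)
    runs <- hits %>% group_by(.data$feature_row) %>%
      summarise(run = longest_consecutive(.data$index), .groups = "drop") %>%
      filter(.data$run >= params$min_consecutive_isotopes)
    if (nrow(runs) == 0) next
    out[[s]] <- tibble(feature = feats$feature[runs$feature_row],
                       rt_ref = feats$rt_apex[runs$feature_row],
                       rt_target = sc$rt[s],
                       n_isotopes_matched = as.integer(runs$run))
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) empty else res
}

# longest run of consecutive integers in a sorted-unique sense
longest_consecutive <- function(idx) {
  idx <- sort(unique(idx))
  if (length(idx) == 0) return(0L)
  max(tabulate(cumsum(c(1L, as.integer(diff(idx) > 1L)))))
}

#' Coarse robust linear fit of alignment candidates
#'
#' Fits a line through the dense candidate band by iteratively reweighted
#' least squares with Tukey bisquare weights (5 iterations,
#' c = 4.685 x MAD-based sigma), then removes candidates whose residual
#' exceeds one standard deviation of the residuals.
#'
#' @param candidates Candidate tibble from [find_alignment_candidates()].
#' @param params [align_params()].
#' @return List: slope, intercept, inliers (tibble), residual_sd.
#' @export
coarse_linear_fit <- function(candidates, params = align_params()) {
  if (nrow(candidates) < params$min_candidates) {
    abort("insufficient alignment evidence")
  }
  x <- candidates$rt_ref; y <- candidates$rt_target
  w <- rep(1, length(x))
  for (it in 1:5) {
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    r <- y - drop(cbind(1, x) %*% fit$coefficients)
    s <- mad(r, center = 0)
    if (s <= 0) s <- max(sd(r), 1e-9)
    u <- r / (4.685 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(w == 0)) w <- rep(1, length(x))
  }
  cf <- fit$coefficients
  r <- y - (cf[1] + cf[2] * x)
  keep <- abs(r) <= max(sd(r), 1e-6)  # epsilon keeps exact fits intact
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       inliers = candidates[keep, ], residual_sd = sd(r))
}

#' Piecewise-linear retention-time mapping
#'
#' Continuous piecewise-linear least squares with `n_segments` equal-quantile
#' knots over reference retention time (linear spline basis). Monotonicity is
#' enforced by merging knots of decreasing segments and refitting;
#' per-knot residual SDs are stored for the tolerance window. Degenerate
#' spans fall back to the coarse line.
#'
#' @param inliers Inlier candidates (tibble with rt_ref, rt_target).
#' @param params [align_params()].
#' @return Object of class `rt_mapping`: breakpoints, values, knot residual
#'   SDs, `peak_width_extension` and `local_tolerance` (filled by
#'   [tolerance_window()]).
#' @export
piecewise_fit <- function(inliers, params = align_params()) {
  x <- inliers$rt_ref; y <- inliers$rt_target
  n_seg <- max(1L, as.integer(params$n_segments))
  if (length(unique(x)) < 4 || diff(range(x)) <= 0) {
    cf <- coef(lm(y ~ x))
    bp <- range(x) + c(-1, 1)
    return(new_rt_mapping(bp, cf[1] + cf[2] * bp, rep(sd(y - cf[1] - cf[2] * x), 2)))
  }
  repeat {
    knots <- unique(quantile(x, probs = seq(0, 1, length.out = n_seg + 1),
                             names = FALSE))
    if (length(knots) < 2) {
      cf <- coef(lm(y ~ x))
      return(new_rt_mapping(range(x), cf[1] + cf[2] * range(x),
                            rep(sd(y - cf[1] - cf[2] * x), 2)))
    }
    B <- spline_basis(x, knots)
    fit <- stats::lm.fit(B, y)
    if (anyNA(fit$coefficients)) {
      # rank-deficient basis (sparse or tied data): drop a segment and retry
      if (n_seg == 1L) {
        cf <- coef(lm(y ~ x))
        return(new_rt_mapping(range(x), cf[1] + cf[2] * range(x),
                              rep(sd(y - cf[1] - cf[2] * x), 2)))
      }
      n_seg <- n_seg - 1L
      next
    }
    vals <- drop(spline_basis(knots, knots) %*% fit$coefficients)
    if (all(diff(vals) >= 0) || n_seg == 1L) break
    n_seg <- n_seg - 1L  # merge segments until the mapping is nondecreasing
  }
  resid <- y - drop(B %*% fit$coefficients)
  seg_of <- pmin(pmax(findInterval(x, knots), 1L), length(knots) - 1L)
  knot_sd <- vapply(seq_along(knots), function(k) {
    near <- resid[seg_of == k - 1L | seg_of == k]
    if (length(near) < 2) sd(resid) else sd(near)
  }, 0)
  knot_sd[!is.finite(knot_sd)] <- sd(resid)
  new_rt_mapping(knots, vals, knot_sd)
}

# linear spline basis: intercept, x, hinges at interior knots
spline_basis <- function(x, knots) {
  interior <- knots[-c(1, length(knots))]
  B <- cbind(1, x)
  for (k in interior) B <- cbind(B, pmax(x - k, 0))
  B
}

new_rt_mapping <- function(breakpoints, values, knot_sd,
                           peak_width_extension = 0, local_tolerance = NULL) {
  structure(list(breakpoints = as.numeric(breakpoints),
                 values = as.numeric(values),
                 knot_sd = as.numeric(knot_sd),
                 peak_width_extension = peak_width_extension,
                 local_tolerance = local_tolerance),
            class = "rt_mapping")
}

#' Map reference retention times to the target map
#'
#' Piecewise-linear interpolation between breakpoints, linear extrapolation
#' beyond the ends using the terminal segment slopes.
#'
#' @param object An `rt_mapping`.
#' @param rt Reference retention times (s). Defaults to the breakpoints.
#' @param ... Unused.
#' @return Mapped retention times in the target map (s).
#' @export
predict.rt_mapping <- function(object, rt = object$breakpoints, ...) {
  bp <- object$breakpoints; v <- object$values
  out <- approx(bp, v, xout = rt, rule = 2)$y
  nb <- length(bp)
  if (nb >= 2) {
    sl_lo <- (v[2] - v[1]) / (bp[2] - bp[1])
    sl_hi <- (v[nb] - v[nb - 1]) / (bp[nb] - bp[nb - 1])
    below <- rt < bp[1]; above <- rt > bp[nb]
    out[below] <- v[1] + sl_lo * (rt[below] - bp[1])
    out[above] <- v[nb] + sl_hi * (rt[above] - bp[nb])
  }
  out
}

#' Fill the locally adjusted tolerance window
#'
#' Sets the per-knot tolerance half-width to
#' `max(floor, k * residual_SD(knot))` and records the reference peak width
#' by which mapped elution boundaries are extended. Regions where the mapping
#' fits poorly get a wider window, so their alignment is more permissive.
#'
#' @param mapping An `rt_mapping` from [piecewise_fit()].
#' @param ref_peak_width Reference elution peak width (s) added on both sides
#'   of the mapped elution interval.
#' @param params [align_params()] (floor and k multiplier).
#' @return The mapping with `local_tolerance` and `peak_width_extension` set.
#' @export
tolerance_window <- function(mapping, ref_peak_width = 0, params = align_params()) {
  mapping$local_tolerance <- pmax(params$tolerance_floor_s,
                                  params$k_tolerance * mapping$knot_sd)
  mapping$peak_width_extension <- ref_peak_width
  mapping
}

#' Local tolerance half-width at reference retention times
#'
#' @param mapping An `rt_mapping` with tolerances filled.
#' @param rt Reference retention times.
#' @return Tolerance half-widths (s).
#' @export
local_tolerance <- function(mapping, rt) {
  if (is.null(mapping$local_tolerance)) abort("tolerance window not set; run tolerance_window()")
  approx(mapping$breakpoints, mapping$local_tolerance, xout = rt, rule = 2)$y
}

#' Align a deuterated map to the reference features
#'
#' Candidate search, robust coarse fit with one-SD filtering, piecewise
#' linear regression and tolerance-window construction in one call.
#'
#' @param ref_features Reference feature tibble (see
#'   [find_alignment_candidates()]).
#' @param target_map Deuterated `lcms_map`.
#' @param ref_peak_width Reference elution peak width (s).
#' @param params [align_params()].
#' @return An `rt_mapping` with tolerances filled; the candidate and inlier
#'   sets are attached as attributes `candidates` and `inliers`.
#' @export
align_map <- function(ref_features, target_map, ref_peak_width = 0,
                      params = align_params()) {
  cand <- find_alignment_candidates(ref_features, target_map, params)
  coarse <- coarse_linear_fit(cand, params)
  mapping <- piecewise_fit(coarse$inliers, params)
  # refinement: the coarse line underfits a curved mapping, so its one-SD cut
  # can drop genuine candidates near the retention-time extremes. Re-admit all
  # candidates consistent with the current piecewise fit, collapse each
  # feature's run of matching scans to its median target time (the elution
  # centroid, immune to window-truncation bias), and refit on those
  # feature-level correspondences.
  inliers <- coarse$inliers
  for (pass in 1:2) {
    r <- cand$rt_target - predict(mapping, cand$rt_ref)
    s_rob <- mad(r)
    if (!is.finite(s_rob) || s_rob <= 0) s_rob <- max(sd(r), 1e-9)
    keep <- abs(r) <= max(2 * s_rob, params$tolerance_floor_s)
    if (sum(keep) < params$min_candidates) break
    inliers <- cand[keep, ]
    pts <- inliers %>% group_by(.data$feature) %>%
      summarise(rt_ref = first(.data$rt_ref),
                rt_target = median(.data$rt_target), .groups = "drop")
    if (nrow(pts) < params$min_candidates) break
    mapping <- piecewise_fit(pts, params)
  }
  mapping <- tolerance_window(mapping, ref_peak_width, params)
  attr(mapping, "candidates") <- cand
  attr(mapping, "inliers") <- inliers
  attr(mapping, "coarse") <- coarse[c("slope", "intercept", "residual_sd")]
  mapping
}

#' @export
print.rt_mapping <- function(x, ...) {
  cat(sprintf("<rt_mapping> %d breakpoints over rt %.1f-%.1f s%s\n",
              length(x$breakpoints), min(x$breakpoints), max(x$breakpoints),
              if (!is.null(x$local_tolerance))
                sprintf(", mean tolerance %.1f s", mean(x$local_tolerance))
              else ""))
  invisible(x)
}
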