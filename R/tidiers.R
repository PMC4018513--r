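#' Tidy a retention-time mapping
#'
#' @param x An `rt_mapping`.
#' @param ... Unused.
#' @return Tibble with one row per breakpoint: rt_ref, rt_target,
#'   residual_sd, tolerance.
#' @export
tidy.rt_mapping <- function(x, ...) {
  tibble(rt_ref = x$breakpoints, rt_target = x$values,
         residual_sd = x$knot_sd,
         tolerance = x$local_tolerance %||% rep(NA_real_, length(x$breakpoints)))
}

#' One-row summary of a retention-time mapping
#'
#' @param x An `rt_mapping`.
#' @param ... Unused.
#' @return Tibble: n_breakpoints, rt_min, rt_max, mean_tolerance,
#'   peak_width_extension, n_candidates, n_inliers.
#' @export
glance.rt_mapping <- function(x, ...) {
  cand <- attr(x, "candidates")
  inl <- attr(x, "inliers")
  tibble(n_breakpoints = length(x$breakpoints),
         rt_min = min(x$breakpoints), rt_max = max(x$breakpoints),
         mean_tolerance = if (is.null(x$local_tolerance)) NA_real_
                          else mean(x$local_tolerance),
         peak_width_extension = x$peak_width_extension,
         n_candidates = if (is.null(cand)) NA_integer_ else nrow(cand),
         n_inliers = if (is.null(inl)) NA_integer_ else nrow(inl))
}

#' Tidy a deuteration distribution
#'
#' @param x A `deut_dist`.
#' @param ... Unused.
#' @return Tibble: state (deuterons), weight.
#' @export
tidy.deut_dist <- function(x, ...) {
  tibble(state = 0:x$n_states, weight = x$weights)
}

#' One-row summary of a deuteration distribution
#'
#' @param x A `deut_dist`.
#' @param ... Unused.
#' @return Tibble: n_states, centroid, centroid_da, iterations, converged.
#' @export
glance.deut_dist <- function(x, ...) {
  tibble(n_states = x$n_states, centroid = x$centroid,
         centroid_da = x$centroid_da, iterations = x$iterations,
         converged = x$converged)
}

#' Tidy an isotope pattern
#'
#' @param x An `isotope_pattern`.
#' @param ... Unused.
#' @return Tibble: index, mz, intensity.
#' @export
tidy.isotope_pattern <- function(x, ...) {
  tibble(index = seq_along(x$intensities) - 1L,
         mz = x$mono_mz + (seq_along(x$intensities) - 1L) * x$spacing,
         intensity = x$intensities)
}
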