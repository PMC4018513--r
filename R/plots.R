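#' Plot a retention-time mapping
#'
#' Shows alignment candidates, surviving inliers, the fitted piecewise-linear
#' mapping and the locally adjusted tolerance band.
#'
#' @param object An `rt_mapping` from [align_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rt_mapping <- function(object, ...) {
  td <- tidy(object)
  grid <- tibble(rt_ref = seq(min(td$rt_ref), max(td$rt_ref), length.out = 200))
  grid$rt_target <- predict(object, grid$rt_ref)
  grid$tol <- if (is.null(object$local_tolerance)) 0
              else local_tolerance(object, grid$rt_ref)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$rt_ref))
  cand <- attr(object, "candidates")
  if (!is.null(cand)) {
    p <- p + ggplot2::geom_point(data = cand,
                                 ggplot2::aes(y = .data$rt_target),
                                 colour = "grey70", size = 0.5)
  }
  inl <- attr(object, "inliers")
  if (!is.null(inl)) {
    p <- p + ggplot2::geom_point(data = inl,
                                 ggplot2::aes(y = .data$rt_target),
                                 colour = "steelblue", size = 0.6)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rt_target - .data$tol,
                                      ymax = .data$rt_target + .data$tol),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rt_target)) +
    ggplot2::labs(x = "reference rt (s)", y = "target rt (s)",
                  title = "Retention-time alignment")
}

#' Plot a deuteration distribution
#'
#' @param object A `deut_dist`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deut_dist <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$state, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$centroid, linetype = "dashed") +
    ggplot2::labs(x = "incorporated deuterons", y = "weight",
                  title = sprintf("Deuteration distribution (centroid %.2f D)",
                                  object$centroid))
}

#' Plot an isotope pattern
#'
#' @param object An `isotope_pattern`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.isotope_pattern <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$mz, ymax = .data$intensity,
                                   ymin = 0)) +
    ggplot2::geom_linerange() +
    ggplot2::labs(x = "m/z (Th)", y = "relative intensity")
}

#' Plot deuteration uptake time series
#'
#' One panel per peptide, mean +/- SD over replicates against incubation
#' time (log scale).
#'
#' @param merged Merged results tibble (`run$merged`).
#' @param peptides Optional character vector of sequences to show.
#' @return A ggplot.
#' @export
plot_uptake <- function(merged, peptides = NULL) {
  df <- as_tibble(merged)
  if (!is.null(peptides)) df <- df[df$sequence %in% peptides, ]
  df$label <- sprintf("%s (%d-%d, z%d)", df$sequence, df$start, df$end,
                      df$charge)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean_centroid)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_centroid - .data$sd_centroid,
      ymax = .data$mean_centroid + .data$sd_centroid)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "incubation time (s)", y = "deuteration centroid (D)")
}
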