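# Scan figures.

#' Plot a windowed delta SNP-index scan
#'
#' Windowed mean delta along each chromosome, with the simulated confidence
#' bands (interpolated at each window's mean depth) and called candidate
#' regions shaded.
#'
#' @param windows Windowed track from [window_smooth()].
#' @param bands Optional `anthomap_ci` bands.
#' @param regions Optional region tibble from [call_regions()].
#' @return A ggplot object.
#' @export
plot_delta_scan <- function(windows, bands = NULL, regions = NULL) {
  w <- filter(windows, .data$usable)
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$mid_bp / 1e6,
                                       y = .data$mean_delta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~chrom, nrow = 3, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(Delta * " SNP-index")) +
    ggplot2::theme_minimal()
  if (!is.null(bands)) {
    for (lev in unique(bands$level)) {
      thr <- band_at(bands, w$mean_depth, lev)
      bd <- bind_cols(w, thr)
      p <- p +
        ggplot2::geom_line(data = bd, ggplot2::aes(y = .data$upper),
                           colour = if (lev <= 0.01) "red" else "blue",
                           linetype = 2) +
        ggplot2::geom_line(data = bd, ggplot2::aes(y = .data$lower),
                           colour = if (lev <= 0.01) "red" else "blue",
                           linetype = 2)
    }
  }
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start_bp / 1e6, xmax = .data$end_bp / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "tomato", alpha = 0.15
    )
  }
  p
}

#' @export
autoplot.anthomap_campaign <- function(object, ...) {
  plot_delta_scan(object$f2$windows, object$bands,
                  bind_rows(object$f2$regions_005, object$f2$regions_001))
}
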