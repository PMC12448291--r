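# ggplot2 methods for the package's result objects. Each autoplot returns
# a plain ggplot so callers can restyle it.

#' @describeIn fit_monod Dose-response points and the fitted Monod curve on
#'   a log concentration axis (the zero-concentration condition is plotted
#'   at a tenth of the smallest positive concentration, hollow).
#' @param object,x A `monod_fit` object.
#' @param ... Unused.
#' @method autoplot monod_fit
#' @export
autoplot.monod_fit <- function(object, ...) {
  df <- object$data
  pos <- df$S > 0
  pseudo <- min(df$S[pos]) / 10
  df$S_plot <- ifelse(pos, df$S, pseudo)
  curve <- tibble::tibble(
    S = 10^seq(log10(pseudo), log10(max(df$S)), length.out = 200)
  )
  curve$r <- predict(object, curve$S)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$S_plot, y = .data$r)) +
    ggplot2::geom_point(ggplot2::aes(shape = pos), show.legend = FALSE) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$S, y = .data$r)) +
    ggplot2::geom_vline(xintercept = object$half_saturation, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Vitamin concentration (M)",
                  y = expression(Growth~rate~(h^-1)),
                  title = sprintf("Monod fit: K[S] = %.3g M", object$half_saturation))
}

#' @describeIn fit_powerlaw_yield Calibration points and fitted power law
#'   on log-log axes.
#' @param object,x A `powerlaw_fit` object.
#' @param ... Unused.
#' @method autoplot powerlaw_fit
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  df <- object$data
  line <- tibble::tibble(
    C = 10^seq(log10(object$valid_range[1]), log10(object$valid_range[2]),
               length.out = 100)
  )
  line$yield <- object$a * line$C^object$b
  ggplot2::ggplot(df, ggplot2::aes(x = .data$C, y = .data$yield)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Vitamin concentration (M)", y = "Yield (OD)",
                  title = sprintf("Power-law yield: a = %.3g, b = %.3g",
                                  object$a, object$b))
}

#' @describeIn sweep_release_rate Normalized auxotroph growth across the
#'   release-rate grid, with the optimum marked.
#' @param object,x A `release_sweep` object.
#' @param ... Unused.
#' @method autoplot release_sweep
#' @export
autoplot.release_sweep <- function(object, ...) {
  xlab <- if (object$mode == "lysis") {
    expression(Lysis~rate~mu~(h^-1))
  } else {
    expression(Secretion~rate~s~(molecules~cell^-1~s^-1))
  }
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$rate, y = .data$normalized_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$optimum_rate, linetype = "dashed") +
    ggplot2::labs(x = xlab, y = "Normalized auxotroph growth",
                  title = sprintf("Optimal %s rate: %.3g",
                                  object$mode, object$optimum_rate))
}

#' @describeIn compute_phase_diagram Shaded trait-plane raster with the
#'   retained growth contours, log axes; pass `traits_points` (a data frame
#'   with `ks_molar`, `quota`, and optionally `label`) to overlay measured
#'   auxotroph traits.
#' @param object,x A `phase_diagram` object.
#' @param traits_points Optional data frame of trait points to overlay.
#' @param ... Unused.
#' @method autoplot phase_diagram
#' @export
autoplot.phase_diagram <- function(object, traits_points = NULL, ...) {
  p <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(x = .data$ks_molar, y = .data$quota)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$normalized_growth)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$normalized_growth),
                          breaks = object$levels, colour = "white") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = expression(K[S]~(M)),
      y = expression(Quota~Y[vit]^-1~(molecules/cell)),
      fill = "Normalized\ngrowth",
      title = sprintf("Auxotroph growth via %s", object$mode)
    )
  if (!is.null(traits_points)) {
    p <- p + ggplot2::geom_point(data = traits_points, colour = "red") +
      (if ("label" %in% names(traits_points)) {
        ggplot2::geom_text(data = traits_points,
                           ggplot2::aes(label = .data$label),
                           colour = "red", vjust = -0.8, size = 3)
      } else NULL)
  }
  p
}

#' Histogram of screen growth deficits
#'
#' Shows the distribution of growth-deficit values across a screened plate
#' with the classification cutoff marked — the view on which the cutoff is
#' chosen.
#'
#' @param results Tibble from [classify_screen()].
#' @param cutoff Cutoff to mark (default -0.4).
#' @returns A ggplot.
#' @export
plot_screen_deficits <- function(results, cutoff = -0.4) {
  ok <- dplyr::filter(results, .data$status == "ok")
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$growth_deficit)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed", colour = "red") +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "Growth deficit (-V vs +V)", y = "Isolates")
}
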