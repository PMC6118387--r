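#' @name plots
#' @title Plotting concentration-time profiles and comparisons
#' @description ggplot2 helpers mirroring the standard presentation of
#' bioequivalence-style profile figures: referent mean with +/- 1 SD error
#' bars and the simulated mean overlaid.
NULL

#' Plot a simulated summary profile, optionally against a referent
#'
#' @param summary Simulated summary profile (`time`, `mean`, optionally `sd`)
#'   as from [summarize_profiles()].
#' @param referent Optional referent profile (`time`, `mean`, `sd`).
#' @param drug Optional label for the title.
#' @return A ggplot object.
#' @export
plot_profiles <- function(summary, referent = NULL, drug = NULL) {
  p <- ggplot2::ggplot(summary, ggplot2::aes(x = .data$time, y = .data$mean))
  if (!is.null(referent)) {
    p <- p +
      ggplot2::geom_errorbar(
        data = referent,
        ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
        width = 0.3, colour = "grey40") +
      ggplot2::geom_point(data = referent, shape = 17, colour = "grey25",
                          size = 2)
  } else if (!is.null(summary$sd)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.3, colour = "steelblue")
  }
  p +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "Time (h)", y = "Concentration (ng/mL)",
                  title = drug,
                  subtitle = if (!is.null(referent))
                    "referent mean ± 1 SD (triangles) vs simulated mean (circles)"
                  else NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname nca
#' @param object An `oralsim_pk` object.
#' @export
autoplot.oralsim_pk <- function(object, ...) {
  prof <- object$profile
  term <- object$terminal_points
  kel <- object$params$Kel
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$time, y = .data$concentration)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_point(data = term, colour = "firebrick") +
    ggplot2::labs(x = "Time (h)", y = "Concentration (ng/mL)",
                  subtitle = sprintf("Kel %.3f 1/h, terminal points in red",
                                     kel)) +
    ggplot2::theme_minimal()
  p
}

#' @rdname bioavailability_experiment
#' @param object An `oralsim_bioavailability` object.
#' @export
autoplot.oralsim_bioavailability <- function(object, ...) {
  long <- tidyr::pivot_longer(object$by_replicate,
                              c("F", "FaFg", "Fh"),
                              names_to = "quantity", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$quantity, y = .data$percent)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "Percent",
                  title = sprintf("Bioavailability decomposition: %s",
                                  object$drug)) +
    ggplot2::theme_minimal()
}
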