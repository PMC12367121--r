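#' @export
autoplot.fhn_trajectory <- function(object, ...) {
  df <- tibble(
    t = rep(object$t, 2),
    value = c(object$V, object$W),
    variable = rep(c("V", "W"), each = nrow(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$variable)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = sprintf("%s model (%s backend)",
                                  attr(object, "model"),
                                  attr(object, "backend"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fhn_bifurcation <- function(object, ...) {
  sweep <- attr(object, "sweep")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$param, y = .data$peak)) +
    ggplot2::geom_point(size = 0.1, alpha = 0.4) +
    ggplot2::labs(
      x = if (sweep == "I_in") "drive amplitude (mA)" else "drive frequency",
      y = "V peak values",
      title = sprintf("bifurcation diagram, %s model", attr(object, "model"))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spike_raster <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$neuron)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "time (ms)", y = "neuron",
                  title = sprintf("raster, %s model", attr(object, "model"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fhn_hopf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$I)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$V_min, ymax = .data$V_max),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$V_star,
                                    linetype = .data$stability)) +
    ggplot2::labs(x = "input current (mA)", y = "V",
                  title = "equilibrium branch and orbit extrema") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fhn_orbit <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$V, y = .data$W)) +
    ggplot2::geom_path(linewidth = 0.2, alpha = 0.7) +
    ggplot2::labs(x = "V", y = "W", title = "phase-plane orbit") +
    ggplot2::theme_minimal()
}
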