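#' Pressure-radius and pressure-force figures
#'
#' Quick-look ggplot helpers for simulated predictions ([simulate_protocol()])
#' or experiment datasets ([generate_experiment()], [load_experiment_table()]).
#' Predictions are drawn as lines, datasets as points; the activation state
#' maps to colour and the axial stretch to the linetype/shape.
#'
#' @param x An `artery_predictions` or `artery_dataset` tibble.
#' @return A ggplot object.
#' @export
plot_pressure_radius <- function(x) {
  pressure_channel_plot(x, "r_outer_mm", "Outer radius (mm)")
}

#' @rdname plot_pressure_radius
#' @export
plot_pressure_force <- function(x) {
  pressure_channel_plot(x, "axial_force_mN", "Axial force (mN)")
}

pressure_channel_plot <- function(x, channel, ylab) {
  p <- ggplot2::ggplot(
    x,
    ggplot2::aes(
      x = .data$pressure_mmHg, y = .data[[channel]],
      colour = .data$state
    )
  )
  p <- if (inherits(x, "artery_predictions")) {
    p + ggplot2::geom_line(ggplot2::aes(linetype = factor(.data$lambda_z)))
  } else {
    p + ggplot2::geom_point(ggplot2::aes(shape = factor(.data$lambda_z)))
  }
  p + ggplot2::labs(
    x = "Pressure (mmHg)", y = ylab,
    linetype = "lambda_z", shape = "lambda_z", colour = "state"
  ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_pressure_radius
#' @param object,... Autoplot interface (object of the documented class).
#' @export
autoplot.artery_predictions <- function(object, ...) {
  combine_pressure_plots(object)
}

#' @rdname plot_pressure_radius
#' @export
autoplot.artery_dataset <- function(object, ...) {
  combine_pressure_plots(object)
}

combine_pressure_plots <- function(x) {
  long <- tidyr::pivot_longer(
    as_tibble(x),
    c("r_outer_mm", "axial_force_mN"),
    names_to = "channel", values_to = "value"
  )
  geom <- if (inherits(x, "artery_predictions")) {
    ggplot2::geom_line(ggplot2::aes(linetype = factor(.data$lambda_z)))
  } else {
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$lambda_z)))
  }
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$pressure_mmHg, y = .data$value, colour = .data$state)
  ) +
    geom +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(
      x = "Pressure (mmHg)", y = NULL,
      linetype = "lambda_z", shape = "lambda_z"
    ) +
    ggplot2::theme_minimal()
}

#' Transmural stress profile figure
#'
#' @param object An `artery_profile` from [transmural_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.artery_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    c("sigma_rr_MPa", "sigma_tt_MPa", "sigma_zz_MPa"),
    names_to = "component", values_to = "stress_MPa"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$r_mm, y = .data$stress_MPa, colour = .data$component)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Loaded radius (mm)", y = "Cauchy stress (MPa)") +
    ggplot2::theme_minimal()
}

#' Fit diagnostics figure: data against fitted forward predictions
#'
#' @param object An `artery_fit` from [fit_parameters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.artery_fit <- function(object, ...) {
  pred <- simulate_protocol(
    object$model,
    pressures = sort(unique(object$data$pressure_mmHg)),
    stretches = sort(unique(object$data$lambda_z)),
    states = unique(object$data$state)
  )
  long_d <- tidyr::pivot_longer(
    as_tibble(object$data),
    c("r_outer_mm", "axial_force_mN"),
    names_to = "channel", values_to = "value"
  )
  long_p <- tidyr::pivot_longer(
    as_tibble(pred),
    c("r_outer_mm", "axial_force_mN"),
    names_to = "channel", values_to = "value"
  )
  ggplot2::ggplot(
    long_d,
    ggplot2::aes(
      x = .data$pressure_mmHg, y = .data$value, colour = .data$state,
      group = interaction(.data$state, .data$lambda_z)
    )
  ) +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$lambda_z))) +
    ggplot2::geom_line(data = long_p, ggplot2::aes(linetype = factor(.data$lambda_z))) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(
      x = "Pressure (mmHg)", y = NULL, shape = "lambda_z",
      linetype = "lambda_z"
    ) +
    ggplot2::theme_minimal()
}
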