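#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted response model
#'
#' @param x A `dpps_fit`.
#' @param ... Unused.
#' @return One row per fitted parameter (`a`, `b`, `c_grav`) with columns
#'   `term` and `estimate`.
#' @method tidy dpps_fit
#' @export
tidy.dpps_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c_grav"),
    estimate = c(x$a, x$b, x$c_grav)
  )
}

#' @rdname tidy.dpps_fit
#' @return `glance()`: a one-row tibble with `geometry`, `chi2`, `dof`,
#'   `gof`, `p_value`, `accepted`, `n_informative`, `convergence`.
#' @export
glance.dpps_fit <- function(x, ...) {
  tibble::tibble(
    geometry = x$geometry, chi2 = x$chi2, dof = x$dof, gof = x$gof,
    p_value = x$p_value, accepted = x$accepted,
    n_informative = x$n_informative, convergence = x$convergence
  )
}

#' Tidy a geometry comparison
#'
#' @param x A `dpps_comparison`.
#' @param ... Unused.
#' @return The ranked comparison table (geometry, GoF, P value, c_grav,
#'   parameters, acceptance), best fit first.
#' @method tidy dpps_comparison
#' @export
tidy.dpps_comparison <- function(x, ...) {
  x$table
}

#' @rdname tidy.dpps_comparison
#' @return `glance()`: one row naming the best geometry and whether any
#'   model was accepted.
#' @method glance dpps_comparison
#' @export
glance.dpps_comparison <- function(x, ...) {
  tibble::tibble(
    best_geometry = x$table$geometry[1],
    best_gof = x$table$gof[1],
    best_p_value = x$table$p_value[1],
    n_accepted = sum(x$table$accepted)
  )
}

#' Plot observed versus predicted magnitudes
#'
#' One panel per experiment: normalized per-position means with SEM error
#' bars against the fitted model predictions.
#'
#' @param object A `dpps_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dpps_fit
#' @export
autoplot.dpps_fit <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$experiment))) +
    ggplot2::labs(
      x = "predicted magnitude", y = "observed magnitude",
      colour = "experiment",
      title = paste0(object$geometry, " fit: GoF = ",
                     signif(object$gof, 3),
                     ", P = ", signif(object$p_value, 3))
    )
}

#' Plot a geometry comparison
#'
#' GoF score per candidate geometry, with the acceptance status colour-
#' coded (P > 0.05).
#'
#' @param object A `dpps_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dpps_comparison
#' @export
autoplot.dpps_comparison <- function(object, ...) {
  df <- object$table
  df$geometry <- factor(df$geometry, levels = rev(df$geometry))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gof, y = .data$geometry,
                                   fill = .data$accepted)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "GoF score (chi2 / dof)", y = NULL,
                  fill = "accepted (P > 0.05)")
}

#' Plot a midline slice of a field
#'
#' Raster of the predicted magnitude (or hit probability) on the sagittal
#' slice nearest `y = y_slice`.
#'
#' @param object A `dpps_field` (or `dpps_region`).
#' @param y_slice Slice coordinate, cm.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dpps_field
#' @export
autoplot.dpps_field <- function(object, y_slice = 0, ...) {
  ys <- unique(object$y)
  slice <- object[object$y == ys[which.min(abs(ys - y_slice))], ]
  value <- if ("S" %in% names(slice)) "S" else "p_hat"
  p <- ggplot2::ggplot(slice, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data[[value]])) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm, forward)", y = "z (cm, up)", fill = value)
  if ("inside" %in% names(slice)) {
    p <- p + ggplot2::geom_point(
      data = slice[slice$inside, ], shape = ".", colour = "white"
    )
  }
  p
}

#' @method autoplot dpps_region
#' @export
autoplot.dpps_region <- autoplot.dpps_field

#' @export
plot.dpps_fit <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.dpps_comparison <- function(x, ...) print(autoplot(x, ...))
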