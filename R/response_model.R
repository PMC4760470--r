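#' Linear response parameters
#'
#' The predicted reflex enhancement at threat location r is the linear map
#' `S(r) = a * P(c_grav, r) + b`: hit probability scaled by a response gain
#' `a` (normalized-AUC units per unit probability) plus an offset `b`
#' (normalized-AUC units).
#'
#' @param a Response gain.
#' @param b Response offset.
#' @param c_grav Gravity bias used when evaluating `P`.
#' @return An object of class `response_params`.
#' @export
response_params <- function(a, b, c_grav = 0) {
  vals <- c(a = a, b = b, c_grav = c_grav)
  if (!all(is.finite(vals))) stop("response parameters must be finite", call. = FALSE)
  structure(as.list(vals), class = "response_params")
}

#' Predicted reflex magnitude at threat locations
#'
#' @param points Threat locations (data frame with `x`, `y`, `z`, matrix, or
#'   3-vector).
#' @param params A [response_params()].
#' @param area A [defended_area()].
#' @param model A [trajectory_model()]; its `c_grav` is overridden by
#'   `params$c_grav`.
#' @return A tibble with coordinates, `p_hat`, `mc_se`, and the predicted
#'   magnitude `S`.
#' @examples
#' predict_response(c(20, 0, 0), response_params(1, 0),
#'                  defended_area("face"), trajectory_model(n_rays = 1e4))
#' @export
predict_response <- function(points, params, area, model = trajectory_model()) {
  stopifnot(inherits(params, "response_params"))
  model$c_grav <- params$c_grav
  out <- hit_probability(points, area, model)
  out$S <- params$a * out$p_hat + params$b
  out
}

#' Response field on a grid
#'
#' [hit_field()] mapped through the linear response model; the result feeds
#' [dpps_region()] and [autoplot.dpps_field()].
#'
#' @inheritParams predict_response
#' @param grid A tibble of grid nodes.
#' @return A `dpps_field` tibble with an `S` column.
#' @export
response_field <- function(grid, params, area, model = trajectory_model()) {
  stopifnot(inherits(params, "response_params"))
  model$c_grav <- params$c_grav
  out <- hit_field(grid, area, model)
  out$S <- params$a * out$p_hat + params$b
  attr(out, "params") <- params
  out
}

#' Extract the DPPS region for a cutoff
#'
#' The model predicts a response magnitude everywhere in space; the
#' defensive peripersonal space for a given cutoff is the set of locations
#' where the prediction strictly exceeds it. Regions nest: a larger cutoff
#' always yields a subset of a smaller one.
#'
#' @param field A field tibble with an `S` column (from [response_field()]),
#'   or a `p_hat`-only field in which case `p_hat` is thresholded.
#' @param cutoff Finite threshold on the predicted magnitude.
#' @return The field with a logical `inside` column; class `dpps_region`.
#' @examples
#' f <- tibble::tibble(x = 0, y = 0, z = 0, S = 1)
#' dpps_region(f, cutoff = 0.5)
#' @export
dpps_region <- function(field, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  values <- if ("S" %in% names(field)) field$S else field$p_hat
  if (is.null(values)) stop("field must have an S or p_hat column", call. = FALSE)
  out <- field
  out$inside <- values > cutoff
  attr(out, "cutoff") <- cutoff
  class(out) <- unique(c("dpps_region", class(out)))
  out
}
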