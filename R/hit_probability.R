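#' Trajectory model for threat hitting actions
#'
#' The threat is assumed to make a linear hitting action in a random
#' direction. Direction components are independent Gaussians with unit
#' variance; gravity enters as a shift of the vertical component's mean:
#' with `+z` up, the z-component mean is `-c_grav`, so positive `c_grav`
#' biases trajectories downward.
#'
#' @param c_grav Dimensionless gravity-bias parameter.
#' @param n_rays Number of Monte-Carlo trajectories per evaluation.
#' @param seed Integer RNG seed; a fixed seed makes every probability
#'   estimate reproducible and provides common random numbers across
#'   evaluation points and `c_grav` values.
#' @return An object of class `trajectory_model`.
#' @examples
#' trajectory_model(c_grav = 1.05, n_rays = 1e5, seed = 1)
#' @export
trajectory_model <- function(c_grav = 0, n_rays = 2e6, seed = 1) {
  stopifnot(is.finite(c_grav), n_rays >= 1, is.finite(seed))
  structure(
    list(c_grav = c_grav, n_rays = as.integer(n_rays), seed = as.integer(seed)),
    class = "trajectory_model"
  )
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat("<trajectory_model> c_grav =", x$c_grav, "| n_rays =", x$n_rays,
      "| seed =", x$seed, "\n")
  invisible(x)
}

#' Sample random hitting directions
#'
#' Draws `n` direction vectors with independent standard-normal x and y
#' components and a z component with mean `-c_grav` (unit variance
#' throughout). Directions are used unnormalized: only the ray's line
#' matters for intersection tests.
#'
#' The base sample depends only on `(n, seed)`; the `c_grav` shift is
#' applied to the same base normals, which gives common random numbers
#' across gravity values and makes Monte-Carlo objectives smooth in
#' `c_grav`.
#'
#' @param n Number of directions (>= 1).
#' @param c_grav Gravity bias.
#' @param seed Integer seed.
#' @return An n x 3 numeric matrix.
#' @export
sample_directions <- function(n, c_grav = 0, seed = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  dirs <- matrix(stats::rnorm(3 * n), ncol = 3,
                 dimnames = list(NULL, c("x", "y", "z")))
  dirs[, 3] <- dirs[, 3] - c_grav
  dirs
}

# Save/restore the global RNG state so sampling helpers are pure functions
# of their seed and leave the caller's stream untouched.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Monte-Carlo hit probability
#'
#' Estimates, for each threat location, the probability that a linear
#' hitting action in a random direction intersects the defended area:
#' `P = Omega / 4pi`, with `Omega` the solid angle subtended by the area
#' (exactly so when `c_grav = 0`; with gravity bias the direction
#' distribution is non-uniform and `P` is a weighted solid angle). One
#' direction sample is drawn per call and reused across all points (common
#' random numbers), so fields evaluated in one call are spatially smooth.
#'
#' Points inside the solid get `p_hat = 1` exactly: every trajectory
#' starting inside hits.
#'
#' @param points Threat locations: a data frame with columns `x`, `y`, `z`
#'   (cm), an n x 3 matrix, or a single 3-vector.
#' @param area A [defended_area()].
#' @param model A [trajectory_model()].
#' @return A tibble with the input coordinates plus `p_hat` (probability in
#'   \[0, 1\]), `solid_angle_sr` (`4 * pi * p_hat`, steradians; an effective
#'   solid angle, exact only at `c_grav = 0`), and `mc_se` (binomial
#'   standard error `sqrt(p_hat * (1 - p_hat) / n_rays)`, 0 at interior
#'   points where no sampling occurs).
#' @examples
#' hit_probability(c(20, 0, 0), defended_area("head"),
#'                 trajectory_model(n_rays = 1e4))
#' @export
hit_probability <- function(points, area, model = trajectory_model()) {
  stopifnot(inherits(area, "defended_area"), inherits(model, "trajectory_model"))
  pts <- as_point_matrix(points)
  n_pts <- nrow(pts)
  inside <- area_contains(area, pts)
  p_hat <- numeric(n_pts)
  p_hat[inside] <- 1
  if (any(!inside)) {
    dirs <- sample_directions(model$n_rays, model$c_grav, model$seed)
    for (i in which(!inside)) {
      p_hat[i] <- mean(ray_hits(area, pts[i, ], dirs))
    }
  }
  mc_se <- sqrt(p_hat * (1 - p_hat) / model$n_rays)
  mc_se[inside] <- 0
  tibble::tibble(
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    p_hat = p_hat,
    solid_angle_sr = 4 * pi * p_hat,
    mc_se = mc_se
  )
}

#' Closed-form hit probability for a sphere
#'
#' For uniform directions (`c_grav = 0`) the hit probability of a sphere of
#' radius `R` from distance `d` is the fractional solid angle of the
#' spherical cap bounded by the tangent cone:
#' `P = (1 - sqrt(1 - (R/d)^2)) / 2`, and 1 when `d <= R`. Serves as the
#' independent analytic oracle for the Monte-Carlo estimator.
#'
#' @param radius Sphere radius, cm (> 0).
#' @param distance Distance from the sphere center, cm (> 0). Vectorized.
#' @return Probability in \[0, 1\].
#' @examples
#' analytic_sphere_probability(1, 2) # ~0.06699
#' @export
analytic_sphere_probability <- function(radius, distance) {
  if (any(radius <= 0) || any(distance <= 0)) {
    stop("radius and distance must be positive", call. = FALSE)
  }
  ifelse(distance <= radius, 1,
         (1 - sqrt(1 - (radius / distance)^2)) / 2)
}

#' Regular evaluation grid
#'
#' @param xlim,ylim,zlim Axis ranges, cm. Defaults cover all six
#'   experiments' hand positions.
#' @param step Grid spacing, cm (> 0).
#' @return A tibble of grid nodes with columns `x`, `y`, `z`.
#' @export
field_grid <- function(xlim = c(-30, 70), ylim = c(-50, 50),
                       zlim = c(-50, 50), step = 2) {
  stopifnot(step > 0)
  grid <- expand.grid(
    x = seq(xlim[1], xlim[2], by = step),
    y = seq(ylim[1], ylim[2], by = step),
    z = seq(zlim[1], zlim[2], by = step),
    KEEP.OUT.ATTRS = FALSE
  )
  if (nrow(grid) == 0) stop("empty grid", call. = FALSE)
  tibble::as_tibble(grid)
}

#' Hit-probability field on a grid
#'
#' Evaluates [hit_probability()] at every node of a grid with one shared
#' direction sample, producing a spatially smooth 3-D scalar field suitable
#' for visualization and DPPS region extraction.
#'
#' @param grid A tibble of nodes (from [field_grid()] or any data frame
#'   with `x`, `y`, `z` columns).
#' @inheritParams hit_probability
#' @return The grid tibble augmented with `p_hat`, `solid_angle_sr`,
#'   `mc_se`; class `dpps_field`.
#' @export
hit_field <- function(grid, area, model = trajectory_model()) {
  if (nrow(grid) == 0) stop("empty grid", call. = FALSE)
  out <- hit_probability(grid, area, model)
  attr(out, "area_name") <- area$name
  attr(out, "model") <- model
  class(out) <- c("dpps_field", class(out))
  out
}

#' Write a field as long-format CSV
#'
#' @param field A field tibble (from [hit_field()] or [predict_response()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_field_csv <- function(field, path) {
  utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}
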