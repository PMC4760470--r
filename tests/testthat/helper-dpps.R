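# Shared fixtures and slow-object cache for the test suite.

# A sphere as a degenerate ellipsoid: the analytic solid-angle oracle applies.
sphere_area <- function(radius = 1, center = c(0, 0, 0)) {
  custom_area(list(clipped_ellipsoid(center, rep(radius, 3))), "sphere")
}

# Dense point-sampling ray oracle: classify a ray by stepping `step` cm along
# it, and report a clearance proxy (approximate minimum distance between the
# sampled ray and the solid's surface) used to recognise near-tangent rays.
dense_ray_oracle <- function(area, origin, direction, tmax = 100, step = 0.01) {
  u <- direction / sqrt(sum(direction^2))
  tt <- seq(0, tmax, by = step)
  pts <- cbind(origin[1] + tt * u[1], origin[2] + tt * u[2],
               origin[3] + tt * u[3])
  hit <- any(area_contains(area, pts))
  clearance <- Inf
  for (comp in area$components) {
    rel <- sweep(pts, 2, comp$center, "-")
    rho <- sqrt(rowSums(sweep(rel, 2, comp$semiaxes, "/")^2))
    nrm <- sqrt(rowSums(rel^2))
    d_ell <- (rho - 1) * nrm / pmax(rho, 1e-12) # signed; <0 inside ellipsoid
    margins <- rep(Inf, nrow(pts))
    viol <- rep(0, nrow(pts))
    for (cl in comp$clips) {
      m <- as.vector(rel %*% cl$normal) - cl$offset
      margins <- pmin(margins, m)
      viol <- pmax(viol, -m)
    }
    inside <- d_ell <= 0 & margins >= 0
    d_surface <- ifelse(inside,
                        pmin(-d_ell, margins),
                        pmax(d_ell, viol))
    clearance <- min(clearance, abs(d_surface))
  }
  list(hit = hit, clearance = clearance)
}

# Chunk-vectorized dense-sampling classifier: hit/miss per ray, stepping
# `step` cm along each ray. Used where thousands of rays are compared
# against the interval method; clearances are computed afterwards for the
# (rare) disagreeing rays only.
dense_ray_classify <- function(area, origins, dirs, tmax = 100, step = 0.01,
                               chunk = 100) {
  n <- nrow(origins)
  lens <- sqrt(rowSums(dirs^2))
  unit <- dirs / lens
  tt <- seq(0, tmax, by = step)
  k <- length(tt)
  hits <- logical(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    m <- length(idx)
    rep_ray <- rep(idx, each = k)
    pts <- origins[rep_ray, , drop = FALSE] +
      unit[rep_ray, , drop = FALSE] * tt
    inside <- area_contains(area, pts)
    hits[idx] <- colSums(matrix(inside, nrow = k)) > 0
  }
  hits
}

# Cache for objects that are slow to build and shared across test files
# (hit-probability grids, replicate studies).
.dpps_test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .dpps_test_cache)) {
    assign(key, build(), envir = .dpps_test_cache)
  }
  get(key, envir = .dpps_test_cache)
}

acceptance_grid_seed <- 101L
acceptance_n_rays <- 1e5

# Hit-probability grids at the informative layout positions, one per
# canonical geometry, shared by the recovery and model-selection suites.
acceptance_grids <- function() {
  cache_get("grids", function() {
    layout <- layout_positions()
    pts <- layout[!layout$anchor, c("x", "y", "z")]
    lapply(
      stats::setNames(nm = c("head", "face", "half_face", "eyes")),
      function(kind) {
        hit_probability_grid(pts, defended_area(kind),
                             n_rays = acceptance_n_rays,
                             seed = acceptance_grid_seed)
      }
    )
  })
}

# Twenty replicate synthetic studies at the default (face, c_grav = 1.05)
# conditions, each normalized and compared across the four geometries.
acceptance_replicates <- function() {
  cache_get("replicates", function() {
    layout <- layout_positions()
    grids <- acceptance_grids()
    lapply(seq_len(20), function(r) {
      cfg <- generative_config(
        n_rays = acceptance_n_rays, ray_seed = acceptance_grid_seed,
        seed = 5000 + r
      )
      trials <- generate_study(cfg, layout)
      dataset <- normalize_dataset(trials, layout)
      comparison <- compare_models(
        dataset,
        fit_config(n_rays = acceptance_n_rays, seed = acceptance_grid_seed),
        grids = grids
      )
      list(config = cfg, dataset = dataset, comparison = comparison)
    })
  })
}
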