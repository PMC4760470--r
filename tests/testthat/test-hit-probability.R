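test_that("direction sampling has the specified moments and is reproducible", {
  n <- 4e5
  tol <- 4 / sqrt(n)
  d0 <- sample_directions(n, c_grav = 0, seed = 2)
  expect_lt(abs(mean(d0[, 1])), tol)
  expect_lt(abs(mean(d0[, 2])), tol)
  expect_lt(abs(mean(d0[, 3])), tol)
  expect_lt(abs(sd(d0[, 3]) - 1), tol)

  d1 <- sample_directions(n, c_grav = 1.05, seed = 2)
  expect_lt(abs(mean(d1[, 3]) + 1.05), tol) # z mean = -c_grav (downward bias)
  expect_equal(d1[, 1:2], d0[, 1:2]) # common random numbers across c_grav

  expect_equal(sample_directions(100, 0.5, seed = 9),
               sample_directions(100, 0.5, seed = 9))
  expect_error(sample_directions(0), ">= 1")
})

test_that("sampling helpers leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- rnorm(3)
  set.seed(123)
  invisible(sample_directions(100, seed = 77))
  expect_equal(rnorm(3), before)
})

test_that("Monte-Carlo estimate matches the analytic sphere solid angle", {
  sph <- sphere_area(1)
  model <- trajectory_model(c_grav = 0, n_rays = 2e5, seed = 4)
  for (d in c(1.5, 2, 5, 10)) {
    res <- hit_probability(c(d, 0, 0), sph, model)
    truth <- analytic_sphere_probability(1, d)
    expect_lt(abs(res$p_hat - truth), 4 * res$mc_se)
  }
})

test_that("interior points are certain hits and the far field vanishes", {
  head <- defended_area("head")
  res_in <- hit_probability(c(0, 0, 0), head, trajectory_model(n_rays = 1e4))
  expect_equal(res_in$p_hat, 1)
  expect_equal(res_in$mc_se, 0)
  expect_equal(res_in$solid_angle_sr, 4 * pi)

  res_far <- hit_probability(c(1000, 0, 0), head,
                             trajectory_model(n_rays = 2e5, seed = 1))
  expect_lt(res_far$p_hat, 1e-4)
})

test_that("the analytic sphere oracle handles its edge cases", {
  expect_equal(analytic_sphere_probability(1, 0.5), 1)
  expect_equal(analytic_sphere_probability(1, 2), (1 - sqrt(0.75)) / 2)
  expect_lt(analytic_sphere_probability(1, 1e6), 1e-9)
  expect_error(analytic_sphere_probability(-1, 2), "positive")
  expect_error(analytic_sphere_probability(1, 0), "positive")
})

test_that("binomial standard error shrinks as 1/sqrt(n)", {
  sph <- sphere_area(1)
  r1 <- hit_probability(c(2, 0, 0), sph, trajectory_model(n_rays = 1e4, seed = 5))
  r2 <- hit_probability(c(2, 0, 0), sph, trajectory_model(n_rays = 1e6, seed = 5))
  expect_equal(r1$mc_se / r2$mc_se, 10, tolerance = 0.1)
})

test_that("fields are y-symmetric and z-symmetric iff unbiased", {
  head <- defended_area("head")
  model0 <- trajectory_model(c_grav = 0, n_rays = 1e5, seed = 6)
  model1 <- trajectory_model(c_grav = 1.05, n_rays = 1e5, seed = 6)
  pts <- tibble::tibble(
    x = c(15, 15, 15, 15), y = c(6, -6, 6, -6), z = c(8, 8, -8, -8)
  )
  for (model in list(model0, model1)) {
    res <- hit_probability(pts, head, model)
    # y-flip pairs agree within MC tolerance at any bias
    se <- 4 * sqrt(res$mc_se[1]^2 + res$mc_se[2]^2)
    expect_lt(abs(res$p_hat[1] - res$p_hat[2]), se)
  }
  res0 <- hit_probability(pts, head, model0)
  res1 <- hit_probability(pts, head, model1)
  # z-flip symmetric without gravity...
  expect_lt(abs(res0$p_hat[1] - res0$p_hat[3]),
            4 * sqrt(res0$mc_se[1]^2 + res0$mc_se[3]^2))
  # ...but broken by the downward bias: points above see more hits
  expect_gt(res1$p_hat[1] - res1$p_hat[3],
            4 * sqrt(res1$mc_se[1]^2 + res1$mc_se[3]^2))
})

test_that("hit probability decays monotonically along the forward axis", {
  head <- defended_area("head")
  res <- hit_probability(tibble::tibble(x = c(15, 20, 30), y = 0, z = 0),
                         head, trajectory_model(n_rays = 1e5, seed = 8))
  expect_true(all(diff(res$p_hat) < 0))
})

test_that("gravity bias monotonically favours points above the head", {
  head <- defended_area("head")
  p_above <- vapply(c(0, 0.5, 1, 1.5), function(cg) {
    hit_probability(c(0, 0, 20), head,
                    trajectory_model(cg, n_rays = 1e5, seed = 10))$p_hat
  }, numeric(1))
  expect_true(all(diff(p_above) >= 0))
})

test_that("nested solids give exactly nested probabilities under CRN", {
  areas <- lapply(
    stats::setNames(nm = c("half_face", "face", "head")), defended_area
  )
  set.seed(20)
  pts <- cbind(runif(12, -20, 30), runif(12, -20, 20), runif(12, -20, 20))
  model <- trajectory_model(c_grav = 0.7, n_rays = 2e4, seed = 12)
  p <- sapply(areas, function(a) hit_probability(pts, a, model)$p_hat)
  expect_true(all(p[, "half_face"] <= p[, "face"]))
  expect_true(all(p[, "face"] <= p[, "head"]))
})

test_that("field grids validate their inputs and cover interior nodes", {
  expect_error(field_grid(step = 0), "step")
  head <- defended_area("head")
  one <- hit_field(tibble::tibble(x = 0, y = 0, z = 0), head,
                   trajectory_model(n_rays = 1e4))
  expect_equal(one$p_hat, 1)
  expect_s3_class(one, "dpps_field")
  expect_error(hit_field(tibble::tibble(x = numeric(), y = numeric(),
                                        z = numeric()),
                         head, trajectory_model(n_rays = 1e4)),
               "empty")
})
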