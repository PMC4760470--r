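make_trials <- function(df) {
  defaults <- tibble::tibble(
    subject = "s1", experiment = 1L, position = "a", eye = "ipsi",
    trial = 1L, auc = 1
  )
  df <- tibble::as_tibble(df)
  for (col in names(defaults)) {
    if (!col %in% names(df)) df[[col]] <- defaults[[col]]
  }
  df
}

test_that("eye pooling averages the available eyes per trial", {
  two <- make_trials(tibble::tibble(eye = c("ipsi", "contra"), auc = c(10, 6)))
  expect_equal(pool_eyes(two)$auc, 8)
  one <- make_trials(tibble::tibble(eye = "ipsi", auc = 5))
  expect_equal(pool_eyes(one)$auc, 5)
  zero <- make_trials(tibble::tibble(eye = c("ipsi", "contra"), auc = c(0, 0)))
  expect_equal(pool_eyes(zero)$auc, 0)
  expect_error(pool_eyes(two[0, ]), "no trial records")
  three <- make_trials(tibble::tibble(eye = c("ipsi", "contra", "ipsi"),
                                      auc = 1))
  expect_error(pool_eyes(three), "more than two")
})

test_that("the power transform is the fourth root", {
  expect_equal(power_transform(16), 2)
  expect_equal(power_transform(0), 0)
  expect_equal(power_transform(0.0625), 0.5)
  expect_error(power_transform(-1), "non-negative")
})

test_that("anchoring shifts each subject to zero at the anchor", {
  layout <- tibble::tibble(
    experiment = 1L, position = c("anchor", "far", "side"),
    anchor = c(TRUE, FALSE, FALSE)
  )
  means <- tibble::tibble(
    subject = "s1", experiment = 1L,
    position = c("anchor", "far", "side"), value = c(5, 3, 2)
  )
  shifted <- shift_to_anchor(means, layout)
  expect_equal(shifted$value[shifted$position == "anchor"], 0)
  expect_equal(sort(shifted$value), c(-3, -2, 0))

  # idempotence: shifting twice equals shifting once
  twice <- shift_to_anchor(shifted, layout)
  expect_equal(twice$value, shifted$value)

  # all-equal data collapses to zeros
  flat <- dplyr::mutate(means, value = 4)
  expect_equal(shift_to_anchor(flat, layout)$value, rep(0, 3))

  # subjects without anchor data are excluded and reported
  no_anchor <- tibble::tibble(
    subject = "s2", experiment = 1L, position = "far", value = 1
  )
  both <- dplyr::bind_rows(means, no_anchor)
  out <- shift_to_anchor(both, layout)
  expect_equal(attr(out, "excluded"), "s2")
  expect_false("s2" %in% out$subject)
})

test_that("experiment rescaling multiplies by y_ref/x_ref and guards zero", {
  expect_equal(rescale_experiment(-1, x_ref = -2, y_ref = -4), -2)
  expect_equal(rescale_experiment(c(0, 1, 2), x_ref = 3, y_ref = 3),
               c(0, 1, 2))
  # zeros (anchors) stay zero under any factor
  expect_equal(rescale_experiment(0, x_ref = 0.3, y_ref = -7), 0)
  expect_error(rescale_experiment(1, x_ref = 0, y_ref = 1), "uninformative")
})

test_that("the distributional gate passes calibrated null data and flags
          planted heteroscedasticity", {
  gen_subject <- function(id, sd_by_pos) {
    purrr::map_dfr(seq_along(sd_by_pos), function(j) {
      tibble::tibble(
        subject = id, experiment = 1L, position = paste0("p", j),
        value = rnorm(10, 1, sd_by_pos[j])
      )
    })
  }

  set.seed(99)
  pass <- replicate(300, {
    g <- check_assumptions(gen_subject("s1", rep(0.2, 5)))
    c(variance = !g$subject_tests$flagged[1],
      normality = g$normality_p > 0.05)
  })
  # each gate is calibrated near its nominal 5% type-I error
  expect_gte(mean(pass["variance", ]), 0.9)
  expect_gte(mean(pass["normality", ]), 0.9)

  set.seed(100)
  planted <- dplyr::bind_rows(
    gen_subject("clean", rep(0.2, 5)),
    gen_subject("noisy", c(0.2, 0.2, 2, 0.2, 0.2)) # 100x variance inflation
  )
  gate <- check_assumptions(planted)
  expect_true("noisy" %in% gate$excluded)
  expect_false("clean" %in% gate$excluded)

  constant <- gen_subject("s1", rep(0.2, 5))
  constant$value <- 1
  degen <- check_assumptions(constant)
  expect_true(degen$degenerate)
  expect_error(
    check_assumptions(tibble::tibble(subject = "s", experiment = 1L,
                                     position = "a", value = 1)),
    ">= 2"
  )
})

test_that("a zero-noise study reproduces the ground-truth means exactly", {
  layout <- layout_positions()
  cfg <- generative_config(
    n_subjects = 2, n_trials = 2, subject_sd = 0, trial_sd = 0, eye_sd = 0,
    n_rays = 5e3, ray_seed = 17, seed = 18
  )
  trials <- generate_study(cfg, layout)
  dataset <- normalize_dataset(trials, layout)
  truth <- ground_truth_means(cfg, layout)
  merged <- dplyr::inner_join(
    tibble::as_tibble(dataset), truth[, c("experiment", "position", "mean")],
    by = c("experiment", "position"), suffix = c("", "_truth")
  )
  expect_equal(merged$mean, merged$mean_truth, tolerance = 1e-12)
  expect_true(all(dataset$mean[dataset$anchor] == 0))
})

test_that("normalization is invariant to trial order and subject relabeling", {
  layout <- layout_positions()
  cfg <- generative_config(n_subjects = 3, n_trials = 3, n_rays = 5e3,
                           ray_seed = 21, seed = 22)
  trials <- generate_study(cfg, layout)
  base <- normalize_dataset(trials, layout)

  set.seed(1)
  shuffled <- trials[sample(nrow(trials)), ]
  expect_equal(tibble::as_tibble(normalize_dataset(shuffled, layout)),
               tibble::as_tibble(base))

  relabeled <- dplyr::mutate(
    trials, subject = paste0("anon_", match(subject, unique(subject)))
  )
  expect_equal(normalize_dataset(relabeled, layout)$mean, base$mean)
})

test_that("experiment-6-only input anchors at zero without rescaling", {
  layout <- layout_positions()
  cfg <- generative_config(n_subjects = 3, n_trials = 3, n_rays = 5e3,
                           ray_seed = 31, seed = 32)
  trials <- generate_study(cfg, layout[layout$experiment == 6, ])
  dataset <- normalize_dataset(trials, layout)
  expect_equal(unique(dataset$experiment), 6L)
  expect_equal(dataset$mean[dataset$anchor], 0)
  expect_null(attr(dataset, "rescale_factors"))
})

test_that("unknown position labels are rejected with the offending labels", {
  layout <- layout_positions()
  bad <- tibble::tibble(
    subject = "s1", experiment = 1L, position = "on-the-moon",
    eye = "ipsi", trial = 1L, auc = 1
  )
  expect_error(normalize_dataset(bad, layout), "on-the-moon")
})

test_that("EMG integration reproduces a hand-computed trapezoid", {
  # 1 s of constant 1 uV at 1 kHz: integrating 0.1-0.2 s gives ~100 uV*ms
  auc <- emg_auc(rep(1, 1000), sampling_rate = 1000, window = c(0.1, 0.2))
  expect_equal(auc, 100)
})
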