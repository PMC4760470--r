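#' Pool the two eyes within each trial
#'
#' Averages the ipsilateral and contralateral AUCs recorded in the same
#' trial (raw scale), improving signal-to-noise; a trial with a single eye
#' record passes through unchanged.
#'
#' @param trials Trial records: a data frame with columns `subject`,
#'   `experiment`, `position`, `eye`, `trial`, `auc`.
#' @return A tibble with one row per trial and column `auc` holding the
#'   pooled value.
#' @examples
#' pool_eyes(tibble::tibble(
#'   subject = "s1", experiment = 1, position = "near",
#'   eye = c("ipsi", "contra"), trial = 1, auc = c(10, 6)
#' ))
#' @export
pool_eyes <- function(trials) {
  required <- c("subject", "experiment", "position", "eye", "trial", "auc")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    stop("trials is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0) stop("no trial records to pool", call. = FALSE)
  pooled <- trials |>
    dplyr::group_by(.data$subject, .data$experiment, .data$position,
                    .data$trial) |>
    dplyr::summarise(
      n_eyes = dplyr::n(), auc = mean(.data$auc), .groups = "drop"
    )
  if (any(pooled$n_eyes > 2)) {
    stop("more than two eye records in a single trial", call. = FALSE)
  }
  dplyr::select(pooled, -"n_eyes")
}

#' Fourth-root power transform
#'
#' `AUC -> AUC^0.25`, the variance-stabilizing transform under which HBR
#' magnitudes are approximately Gaussian with position-independent variance.
#'
#' @param auc Non-negative numeric vector (uV*ms).
#' @param exponent Transform exponent (default 0.25).
#' @return The transformed values.
#' @examples
#' power_transform(16) # 2
#' @export
power_transform <- function(auc, exponent = 0.25) {
  if (any(auc < 0, na.rm = TRUE)) {
    stop("AUC values must be non-negative", call. = FALSE)
  }
  auc^exponent
}

#' Shift each subject's position means to their anchor
#'
#' Subtracts, per subject, the mean at the experiment's anchor position
#' from every position mean, putting all subjects on a common within-
#' experiment origin (the anchor becomes exactly 0). Subjects without
#' anchor data cannot be placed on that origin and are dropped, with their
#' ids recorded in the `"excluded"` attribute.
#'
#' @param subject_means Tibble with columns `subject`, `experiment`,
#'   `position`, `value`.
#' @param layout Layout tibble with `experiment`, `position`, `anchor`.
#' @return The shifted tibble; attribute `"excluded"` lists subjects
#'   lacking anchor data.
#' @export
shift_to_anchor <- function(subject_means, layout) {
  anchors <- layout[layout$anchor, c("experiment", "position")]
  shifted <- subject_means |>
    dplyr::left_join(
      dplyr::mutate(anchors, .anchor = TRUE),
      by = c("experiment", "position")
    ) |>
    dplyr::mutate(.anchor = !is.na(.data$.anchor)) |>
    dplyr::group_by(.data$subject, .data$experiment) |>
    dplyr::mutate(
      .anchor_value = if (any(.data$.anchor)) {
        mean(.data$value[.data$.anchor])
      } else {
        NA_real_
      }
    ) |>
    dplyr::ungroup()
  excluded <- unique(shifted$subject[is.na(shifted$.anchor_value)])
  shifted <- shifted |>
    dplyr::filter(!is.na(.data$.anchor_value)) |>
    dplyr::mutate(value = .data$value - .data$.anchor_value) |>
    dplyr::select(-".anchor", -".anchor_value")
  attr(shifted, "excluded") <- excluded
  shifted
}

#' Rescale one experiment onto the reference experiment's scale
#'
#' Multiplies every value by `y_ref / x_ref`, where `x_ref` is this
#' experiment's mean at a position shared with the reference experiment and
#' `y_ref` is the reference experiment's mean at that same position. Applied
#' to anchored data this maps the shared position onto the reference scale
#' while keeping anchors at exactly 0.
#'
#' @param values Numeric vector of anchored values.
#' @param x_ref This experiment's mean at the shared position (nonzero).
#' @param y_ref The reference experiment's mean at the shared position.
#' @return The rescaled values.
#' @examples
#' rescale_experiment(c(0, -1, -2), x_ref = -2, y_ref = -4)
#' @export
rescale_experiment <- function(values, x_ref, y_ref) {
  if (length(x_ref) != 1 || length(y_ref) != 1) {
    stop("x_ref and y_ref must be single values", call. = FALSE)
  }
  if (x_ref == 0) {
    stop("x_ref is 0: the shared position is uninformative, cannot rescale",
         call. = FALSE)
  }
  values * (y_ref / x_ref)
}

#' Distributional gating of transformed HBR magnitudes
#'
#' Checks the two assumptions behind the chi-square goodness-of-fit
#' machinery on the transformed trial-level data: equal variance across
#' hand positions (Bartlett's test, per subject) and normality (Anderson-
#' Darling test on position-centered residuals, pooled). Subjects whose
#' variance differs across positions at `alpha` are listed for exclusion.
#'
#' @param values Tibble of transformed trial-level data with columns
#'   `subject`, `experiment`, `position`, `value`.
#' @param alpha Significance level of the variance-homogeneity gate.
#' @return An object of class `hbr_gating`: a list with `subject_tests`
#'   (subject, experiment, bartlett_p, flagged), `normality_p` (pooled
#'   Anderson-Darling P), `excluded` (flagged subject ids), and
#'   `degenerate` (TRUE when the data had no variance to test).
#' @export
check_assumptions <- function(values, alpha = 0.05) {
  required <- c("subject", "experiment", "position", "value")
  stopifnot(all(required %in% names(values)))
  counts <- values |>
    dplyr::count(.data$subject, .data$position)
  enough <- values |>
    dplyr::distinct(.data$subject, .data$position) |>
    dplyr::count(.data$subject, name = "n_positions")
  if (all(enough$n_positions < 2) || all(counts$n < 2)) {
    stop("need >= 2 positions with >= 2 observations each", call. = FALSE)
  }
  if (stats::var(values$value) == 0) {
    return(structure(
      list(
        subject_tests = tibble::tibble(
          subject = character(), experiment = integer(),
          bartlett_p = numeric(), flagged = logical()
        ),
        normality_p = NA_real_, excluded = character(), degenerate = TRUE
      ),
      class = "hbr_gating"
    ))
  }
  subject_tests <- values |>
    dplyr::group_by(.data$subject, .data$experiment) |>
    dplyr::group_modify(function(df, key) {
      usable <- df |>
        dplyr::count(.data$position) |>
        dplyr::filter(.data$n >= 2)
      df <- df[df$position %in% usable$position, ]
      p <- if (nrow(usable) < 2 || stats::var(df$value) == 0) {
        NA_real_
      } else {
        stats::bartlett.test(df$value, factor(df$position))$p.value
      }
      tibble::tibble(bartlett_p = p)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(flagged = !is.na(.data$bartlett_p) & .data$bartlett_p < alpha)

  residuals <- values |>
    dplyr::group_by(.data$subject, .data$position) |>
    dplyr::mutate(.resid = .data$value - mean(.data$value)) |>
    dplyr::ungroup() |>
    dplyr::pull(".resid")
  normality_p <- if (length(residuals) >= 8 && stats::var(residuals) > 0) {
    nortest::ad.test(residuals)$p.value
  } else {
    NA_real_
  }
  structure(
    list(
      subject_tests = subject_tests,
      normality_p = normality_p,
      excluded = subject_tests$subject[subject_tests$flagged],
      degenerate = FALSE
    ),
    class = "hbr_gating"
  )
}

#' @export
print.hbr_gating <- function(x, ...) {
  cat("<hbr_gating>\n")
  if (x$degenerate) {
    cat("  degenerate input: no variance to test\n")
    return(invisible(x))
  }
  cat("  pooled Anderson-Darling normality P =", format(x$normality_p), "\n")
  cat("  subjects flagged by Bartlett gate:",
      if (length(x$excluded)) paste(x$excluded, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Normalize a trial-level HBR dataset onto the common scale
#'
#' The full normalization chain: pool the two eyes per trial, apply the
#' fourth-root transform, average trials into per-subject per-position
#' means, shift each subject to their experiment's anchor, rescale
#' experiments 1-5 onto experiment 6's scale through the shared reference
#' positions, and summarise across subjects into per-position means and
#' SEMs. Optionally excludes subjects flagged by [check_assumptions()]
#' first.
#'
#' @param trials Trial records (see [pool_eyes()] for required columns).
#' @param layout Layout tibble from [layout_positions()]; every
#'   `(experiment, position)` in `trials` must appear in it.
#' @param exponent Power-transform exponent.
#' @param gate If `TRUE`, run the distributional gate and drop flagged
#'   subjects before summarising.
#' @param alpha Gate significance level.
#' @return A tibble of class `hbr_dataset` with columns `experiment`,
#'   `position`, `x`, `y`, `z`, `anchor`, `mean`, `sem`, `n_subjects`.
#'   Attributes: `"excluded"` (subjects dropped and why), `"gating"` (the
#'   gate report when `gate = TRUE`), `"rescale_factors"`.
#' @examples
#' cfg <- generative_config(n_subjects = 2, n_trials = 3, n_rays = 1e3)
#' trials <- generate_study(cfg)
#' normalize_dataset(trials, layout_positions())
#' @export
normalize_dataset <- function(trials, layout = layout_positions(),
                              exponent = 0.25, gate = FALSE, alpha = 0.05) {
  key_trials <- unique(paste(trials$experiment, trials$position, sep = "\r"))
  key_layout <- paste(layout$experiment, layout$position, sep = "\r")
  unknown <- setdiff(key_trials, key_layout)
  if (length(unknown) > 0) {
    stop("trial labels absent from layout: ",
         paste(gsub("\r", "/", unknown), collapse = ", "), call. = FALSE)
  }

  pooled <- pool_eyes(trials)
  pooled$value <- power_transform(pooled$auc, exponent)

  gating <- NULL
  excluded <- list()
  if (gate) {
    gating <- check_assumptions(pooled)
    if (length(gating$excluded) > 0) {
      excluded$variance_gate <- gating$excluded
      pooled <- pooled[!pooled$subject %in% gating$excluded, ]
    }
  }

  subject_means <- pooled |>
    dplyr::group_by(.data$subject, .data$experiment, .data$position) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")

  shifted <- shift_to_anchor(subject_means, layout)
  if (length(attr(shifted, "excluded")) > 0) {
    excluded$missing_anchor <- attr(shifted, "excluded")
  }

  # Cross-experiment rescaling through experiment 6's shared positions.
  rescale_factors <- NULL
  experiments <- sort(unique(shifted$experiment))
  if (6 %in% experiments && length(experiments) > 1) {
    exp6_means <- shifted |>
      dplyr::filter(.data$experiment == 6) |>
      dplyr::group_by(.data$position) |>
      dplyr::summarise(y_ref = mean(.data$value), .groups = "drop")
    refs <- layout[layout$ref & layout$experiment %in% experiments, ]
    rescale_factors <- purrr::map_dfr(
      setdiff(experiments, 6),
      function(exp_id) {
        ref_pos <- refs$position[refs$experiment == exp_id]
        if (length(ref_pos) != 1) {
          return(tibble::tibble(experiment = exp_id, factor = 1))
        }
        sub <- shifted[shifted$experiment == exp_id &
                         shifted$position == ref_pos, ]
        x_ref <- mean(sub$value)
        y_ref <- exp6_means$y_ref[match(ref_pos, exp6_means$position)]
        if (is.na(y_ref)) {
          return(tibble::tibble(experiment = exp_id, factor = 1))
        }
        tibble::tibble(
          experiment = exp_id,
          factor = rescale_experiment(1, x_ref, y_ref)
        )
      }
    )
    shifted <- shifted |>
      dplyr::left_join(rescale_factors, by = "experiment") |>
      dplyr::mutate(
        value = .data$value * dplyr::coalesce(.data$factor, 1)
      ) |>
      dplyr::select(-"factor")
  }

  out <- shifted |>
    dplyr::group_by(.data$experiment, .data$position) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()),
      n_subjects = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(sem = ifelse(is.na(.data$sem), 0, .data$sem)) |>
    dplyr::inner_join(
      layout[, c("experiment", "position", "x", "y", "z", "anchor")],
      by = c("experiment", "position")
    ) |>
    dplyr::select("experiment", "position", "x", "y", "z", "anchor",
                  "mean", "sem", "n_subjects") |>
    dplyr::arrange(.data$experiment, .data$position)

  # anchors are exactly 0 by construction; snap away rounding fuzz
  out$mean[out$anchor] <- 0

  attr(out, "excluded") <- excluded
  attr(out, "gating") <- gating
  attr(out, "rescale_factors") <- rescale_factors
  attr(out, "exponent") <- exponent
  class(out) <- c("hbr_dataset", class(out))
  out
}

#' Integrate rectified EMG into an AUC magnitude
#'
#' Optional helper for users starting from raw EMG sweeps rather than
#' precomputed AUCs: rectifies the signal and integrates it over a
#' post-stimulus window by the trapezoidal rule.
#'
#' @param emg Numeric vector, one EMG sweep (uV).
#' @param sampling_rate Samples per second.
#' @param window Integration window, seconds post-stimulus.
#' @param stimulus_index Sample index of stimulus onset.
#' @return The AUC in uV*ms.
#' @export
emg_auc <- function(emg, sampling_rate = 8192, window = c(0.045, 0.180),
                    stimulus_index = 1) {
  stopifnot(sampling_rate > 0, length(window) == 2, window[1] < window[2])
  idx <- stimulus_index + round(window * sampling_rate)
  idx <- pmax(1, pmin(idx, length(emg)))
  seg <- abs(emg[idx[1]:idx[2]])
  dt_ms <- 1000 / sampling_rate
  sum((seg[-1] + seg[-length(seg)]) / 2) * dt_ms
}
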