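#' Configuration for an end-to-end simulated imitation study
#'
#' Bundles the stage configurations; one root seed feeds named
#' sub-streams for composition, performance simulation and analysis.
#'
#' @param composition a [composition_config()].
#' @param synth a [synth_config()] (used only when stimuli are rendered).
#' @param cohort a [cohort_config()].
#' @param large_error_threshold cents threshold for [flag_large_errors()].
#' @param octave_correct whether scoring snaps flagged notes to the
#'   nearest target octave.
#' @param n_boot bootstrap iterations for CIs.
#' @param seed root seed.
#' @param out_dir optional output directory; when set,
#'   [run_end_to_end()] writes CSVs, figures and a manifest there.
#' @return a `run_config` list.
#' @export
run_config <- function(composition = composition_config(), synth = synth_config(),
                       cohort = cohort_config(), large_error_threshold = 1000,
                       octave_correct = FALSE, n_boot = 1000, seed = 1,
                       out_dir = NULL) {
  structure(
    list(
      composition = composition, synth = synth, cohort = cohort,
      large_error_threshold = large_error_threshold,
      octave_correct = octave_correct, n_boot = as.integer(n_boot),
      seed = as.integer(seed), out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Full inferential analysis of a score table
#'
#' Runs the four nested mixed-model analyses (modality and perceptual
#' ability predicting each score type), bootstrap CIs for each
#' standardized estimate, sing-vs-whistle partial correlations of every
#' score controlling for perceptual ability, and the post-hoc
#' target-pitch model.
#'
#' @param scores score table from [score_participants()].
#' @param errors note-error table (for the post-hoc model); may be
#'   `NULL` to skip it.
#' @param n_boot bootstrap iterations (0 skips CIs).
#' @param seed seed for the bootstrap streams.
#' @return list with `effects` (model_result rows, CIs attached),
#'   `partial_correlations` (per score type), and `posthoc`.
#' @export
analyze_scores <- function(scores, errors = NULL, n_boot = 1000, seed = 1) {
  outcomes <- c("note_inaccuracy", "interval_inaccuracy", "note_imprecision", "interval_imprecision")
  eff <- dplyr::bind_rows(lapply(outcomes, function(o) fit_nested_lmm(scores, o)))
  if (n_boot > 0) {
    cis <- dplyr::bind_rows(lapply(outcomes, function(o) {
      dplyr::bind_rows(lapply(c("modality", "mbea_percent"), function(e) {
        bootstrap_ci(scores, o, e,
          n_boot = n_boot,
          seed = derive_seed(seed, paste0("boot_", o, "_", e))
        )
      }))
    }))
    eff <- dplyr::left_join(eff, cis, by = c("outcome", "effect"))
  }

  wide <- tidyr::pivot_wider(
    scores[, c("participant_id", "modality", "mbea_percent", outcomes)],
    names_from = "modality", values_from = dplyr::all_of(outcomes)
  )
  pc <- dplyr::bind_rows(lapply(outcomes, function(o) {
    res <- partial_correlation(
      wide[[paste0(o, "_sing")]], wide[[paste0(o, "_whistle")]],
      controls = wide$mbea_percent
    )
    dplyr::mutate(res, score = o, .before = 1)
  }))

  posthoc <- if (!is.null(errors)) posthoc_target_pitch_model(errors) else NULL
  list(effects = eff, partial_correlations = pc, posthoc = posthoc)
}

#' Run the whole simulated study end to end
#'
#' Composes the two melody sets, simulates the cohort's imitation
#' performances, applies the exclusion filters, scores participants,
#' and runs the inferential stage. With `out_dir` set, writes tidy
#' CSVs (melodies, trials, profiles, exclusions, scores, effects,
#' partial correlations), summary figures and a manifest recording the
#' seed and package version.
#'
#' @param cfg a [run_config()].
#' @return list with `melodies`, `trials`, `profiles`, `filtered`,
#'   `scores`, `errors`, `analysis`, `manifest`.
#' @export
run_end_to_end <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  comp <- cfg$composition
  melodies <- stage("compose", {
    cs <- comp
    cs$seed <- derive_seed(cfg$seed, "melodies_sing")
    cw <- comp
    cw$seed <- derive_seed(cfg$seed, "melodies_whistle")
    list(sing = compose_set(cs), whistle = compose_set(cw))
  })
  sim <- stage("simulate", simulate_study(cfg$cohort, melodies, seed = derive_seed(cfg$seed, "study")))
  filtered <- stage("filter", filter_trials(sim$trials, sim$profiles, n_notes = comp$n_notes))
  scores <- stage("score", score_participants(
    filtered, sim$profiles,
    large_error_threshold = cfg$large_error_threshold,
    octave_correct = cfg$octave_correct
  ))
  errors <- stage("score", {
    fl <- flag_large_errors(note_errors(filtered$kept, sim$profiles),
      threshold = cfg$large_error_threshold, octave_correct = cfg$octave_correct
    )
    fl$errors
  })
  analysis <- stage("analyze", analyze_scores(scores,
    errors = errors,
    n_boot = cfg$n_boot, seed = derive_seed(cfg$seed, "analysis")
  ))
  manifest <- tibble::tibble(
    package = "pitchmimic",
    version = as.character(utils::packageVersion("pitchmimic")),
    seed = cfg$seed,
    n_participants = cfg$cohort$n_participants,
    n_melodies = comp$n_melodies,
    n_notes = comp$n_notes,
    n_trials = nrow(dplyr::distinct(sim$trials[, c("participant_id", "modality", "melody_id")])),
    n_excluded = nrow(filtered$excluded),
    n_boot = cfg$n_boot,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  out <- list(
    melodies = melodies, trials = sim$trials, profiles = sim$profiles,
    filtered = filtered, scores = scores, errors = errors,
    analysis = analysis, manifest = manifest
  )
  if (!is.null(cfg$out_dir)) write_run(out, cfg$out_dir)
  out
}

# Write the run bundle as plain-text CSVs plus figures.
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_csv(x, file.path(out_dir, name))
  w(dplyr::mutate(run$melodies$sing, set = "sing"), "melodies_sing.csv")
  w(dplyr::mutate(run$melodies$whistle, set = "whistle"), "melodies_whistle.csv")
  w(run$trials, "trials.csv")
  w(run$profiles, "profiles.csv")
  w(run$filtered$excluded, "exclusions.csv")
  w(run$scores, "scores.csv")
  w(run$analysis$effects, "effects.csv")
  w(run$analysis$partial_correlations, "partial_correlations.csv")
  if (!is.null(run$analysis$posthoc)) w(run$analysis$posthoc, "posthoc.csv")
  w(run$manifest, "manifest.csv")
  ggplot2::ggsave(file.path(out_dir, "error_distributions.png"),
    plot_error_distributions(run$errors),
    width = 7, height = 4, dpi = 150
  )
  ggplot2::ggsave(file.path(out_dir, "target_pitch_profile.png"),
    plot_target_pitch_profile(run$errors),
    width = 7, height = 4, dpi = 150
  )
  invisible(out_dir)
}

#' Summary figure: note-error distributions by modality
#'
#' @param errors note-error table.
#' @return a ggplot object.
#' @export
plot_error_distributions <- function(errors) {
  ggplot2::ggplot(errors, ggplot2::aes(x = modality, y = error_cents)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.12, outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "note error (cents)") +
    ggplot2::theme_minimal()
}

#' Summary figure: median inaccuracy per target note
#'
#' The compression signature: flat at high targets, sharp at low
#' targets, steeper for singing.
#'
#' @param errors note-error table.
#' @return a ggplot object.
#' @export
plot_target_pitch_profile <- function(errors) {
  agg <- dplyr::summarise(
    dplyr::group_by(errors, modality, pitch_class),
    median_error = stats::median(error_cents),
    q1 = stats::quantile(error_cents, 0.25),
    q3 = stats::quantile(error_cents, 0.75),
    .groups = "drop"
  )
  ggplot2::ggplot(agg, ggplot2::aes(x = pitch_class, y = median_error, colour = modality)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = q1, ymax = q3, fill = modality),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "target note (chromatic degree)", y = "error (cents)") +
    ggplot2::theme_minimal()
}

#' Small-sample bias factor of the sample standard deviation
#'
#' `E[s] = c4(n) * sigma` for the sample SD of `n` normal observations;
#' `c4(n) = sqrt(2/(n-1)) * gamma(n/2) / gamma((n-1)/2)`. Used to
#' de-bias imprecision-based noise-SD estimates in parameter recovery.
#'
#' @param n number of observations (vectorized, `n >= 2`).
#' @return the c4 factor in (0, 1).
#' @export
c4_factor <- function(n) {
  stopifnot(all(n >= 2))
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

# c4-corrected imprecision: mean over classes of s / c4(n_class).
mean_class_sd_debiased <- function(errors, class) {
  n_by <- table(class)
  usable <- names(n_by)[n_by >= 2]
  if (length(usable) == 0) {
    return(NA_real_)
  }
  keep <- as.character(class) %in% usable
  sds <- tapply(errors[keep], as.character(class[keep]), stats::sd)
  ns <- as.numeric(n_by[names(sds)])
  mean(sds / c4_factor(ns))
}

#' Recover generative parameters from a simulated study
#'
#' The acceptance harness for the propagation-of-error model. For each
#' replicate it simulates a study, filters and octave-corrects flagged
#' notes, and estimates, per participant and modality:
#'
#' * `gamma`: minus the OLS slope of note error on target pitch
#'   (compression makes error fall by `gamma` cents per cent of target);
#' * `bias`: the regression intercept minus `gamma_hat * habitual`
#'   (the intercept estimates `bias + gamma * habitual`);
#' * `noise_sd`: the c4-debiased within-class SD of note errors,
#'   estimating `sqrt(perceptual_sd^2 + production_sd^2 + motor_sd^2)`.
#'
#' Estimates are compared against the ground-truth profile parameters.
#'
#' @param cfg a [run_config()]; recovery always scores with octave
#'   correction enabled so injected octave jumps do not contaminate the
#'   noise estimates.
#' @param n_replicates number of independent simulated studies.
#' @param seed root seed.
#' @return list with `per_participant` (one row per replicate x
#'   participant x modality: truth, estimate and error for each
#'   parameter) and `summary` (per parameter x modality: mean estimator
#'   bias and RMSE).
#' @export
recover_parameters <- function(cfg = run_config(), n_replicates = 1, seed = cfg$seed) {
  one_rep <- function(r) {
    rseed <- derive_seed(seed, paste0("recovery", r))
    comp <- cfg$composition
    cs <- comp
    cs$seed <- derive_seed(rseed, "melodies_sing")
    cw <- comp
    cw$seed <- derive_seed(rseed, "melodies_whistle")
    melodies <- list(sing = compose_set(cs), whistle = compose_set(cw))
    sim <- simulate_study(cfg$cohort, melodies, seed = derive_seed(rseed, "study"))
    filtered <- filter_trials(sim$trials, sim$profiles, n_notes = comp$n_notes)
    errs <- flag_large_errors(note_errors(filtered$kept, sim$profiles),
      threshold = cfg$large_error_threshold, octave_correct = TRUE
    )$errors

    est <- dplyr::summarise(
      dplyr::group_by(errs, participant_id, modality),
      gamma_hat = -stats::coef(stats::lm(error_cents ~ target_cents))[2],
      intercept_hat = stats::coef(stats::lm(error_cents ~ target_cents))[1],
      noise_sd_hat = mean_class_sd_debiased(error_cents, pitch_class),
      .groups = "drop"
    )
    truth <- dplyr::mutate(sim$profiles,
      noise_sd_true = sqrt(perceptual_sd^2 + production_sd^2 + motor_sd^2)
    )[, c(
      "participant_id", "modality", "habitual_cents", "bias_cents",
      "gamma", "noise_sd_true"
    )]
    x <- dplyr::inner_join(est, truth, by = c("participant_id", "modality"))
    x$bias_hat <- x$intercept_hat - x$gamma_hat * x$habitual_cents
    tibble::tibble(
      replicate = r,
      participant_id = rep(x$participant_id, 3),
      modality = rep(x$modality, 3),
      parameter = rep(c("gamma", "bias", "noise_sd"), each = nrow(x)),
      truth = c(x$gamma, x$bias_cents, x$noise_sd_true),
      estimate = c(x$gamma_hat, x$bias_hat, x$noise_sd_hat)
    )
  }
  per <- dplyr::bind_rows(lapply(seq_len(n_replicates), one_rep))
  per$error <- per$estimate - per$truth
  summary <- dplyr::summarise(
    dplyr::group_by(per, parameter, modality),
    bias = mean(error), rmse = sqrt(mean(error^2)),
    se_bias = stats::sd(error) / sqrt(dplyr::n()), .groups = "drop"
  )
  list(per_participant = per, summary = summary)
}

#' Standardized effect estimates for one simulated study
#'
#' A light single-replicate evaluation of the study's directional
#' predictions: standardized modality effects on the four scores, the
#' post-hoc target-pitch slope and interaction, and the partial
#' correlations of sing vs whistle scores controlling for perceptual
#' ability. No df machinery — intended for replicate loops (power,
#' sign-recovery and calibration studies).
#'
#' @param scores score table.
#' @param errors note-error table.
#' @return named numeric vector: `note_imprecision_modality`,
#'   `interval_imprecision_modality`, `note_inaccuracy_modality`,
#'   `interval_inaccuracy_modality`, `target_pitch_slope`,
#'   `modality_pitch_interaction`, `note_imprecision_partial_r`,
#'   `interval_imprecision_partial_r`, `note_inaccuracy_partial_r`,
#'   `interval_inaccuracy_partial_r`. Modality contrasts are whistle
#'   minus sing.
#' @export
study_effect_estimates <- function(scores, errors) {
  outcomes <- c("note_imprecision", "interval_imprecision", "note_inaccuracy", "interval_inaccuracy")
  mods <- vapply(outcomes, function(o) {
    standardized_estimates(scores, o)[["modality"]]
  }, numeric(1))

  agg <- dplyr::summarise(
    dplyr::group_by(errors, participant_id, modality, pitch_class),
    mean_error = mean(error_cents), .groups = "drop"
  )
  agg$target_cents <- 100 * agg$pitch_class
  sdat <- standardize_inputs(agg, c("modality", "target_cents"))
  m <- fit_ri_model(mean_error ~ modality * target_cents + (1 | participant_id), sdat)
  b <- if (m$engine == "lmer") lme4::fixef(m$fit) else stats::coef(m$fit)

  wide <- tidyr::pivot_wider(
    scores[, c("participant_id", "modality", "mbea_percent", outcomes)],
    names_from = "modality", values_from = dplyr::all_of(outcomes)
  )
  pr <- vapply(outcomes, function(o) {
    partial_correlation(
      wide[[paste0(o, "_sing")]], wide[[paste0(o, "_whistle")]],
      controls = wide$mbea_percent
    )$r
  }, numeric(1))

  c(
    note_imprecision_modality = unname(mods["note_imprecision"]),
    interval_imprecision_modality = unname(mods["interval_imprecision"]),
    note_inaccuracy_modality = unname(mods["note_inaccuracy"]),
    interval_inaccuracy_modality = unname(mods["interval_inaccuracy"]),
    target_pitch_slope = unname(b["target_cents"]),
    modality_pitch_interaction = unname(b["modality:target_cents"]),
    note_imprecision_partial_r = unname(pr["note_imprecision"]),
    interval_imprecision_partial_r = unname(pr["interval_imprecision"]),
    note_inaccuracy_partial_r = unname(pr["note_inaccuracy"]),
    interval_inaccuracy_partial_r = unname(pr["interval_inaccuracy"])
  )
}

utils::globalVariables(c(
  "perceptual_sd", "production_sd", "motor_sd", "parameter", "median_error", "q1", "q3",
  "gamma_hat", "intercept_hat", "habitual_cents", "bias_cents"
))
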