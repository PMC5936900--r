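#' Population configuration for a simulated imitation cohort
#'
#' Each simulated participant imitates melodies twice, by singing and by
#' whistling. The generative model for one produced note is a
#' propagation-of-error chain with a habitual-pitch attractor:
#'
#' `produced = target + bias_m + gamma_m * (habitual_m - target) + e_perc + e_prod + e_motor_m`
#'
#' where `e_perc ~ N(0, perceptual_sd^2)` is drawn with one SD shared by
#' both modalities within a participant (the common auditory/memory
#' stage), `e_prod ~ N(0, production_sd^2)` is a second shared-SD stage
#' standing for production factors common to both effectors (chiefly
#' respiratory drive) that perceptual ability does not index,
#' `e_motor_m ~ N(0, motor_sd_m^2)` is modality-specific (larynx
#' vs lips/tongue), `bias_m` is a constant flat/sharp offset, and
#' `gamma_m` in `[0, 1)` linearly compresses errors toward the habitual
#' pitch (the "vocal laziness" attractor). With probability
#' `p_octave_error` a produced note jumps a full octave (+/-1200 cents).
#' Per note, `p_omit` and `p_duplicate` drop or repeat notes so that
#' count-based exclusion filters have work to do.
#'
#' All pitch parameters are in cents on the task scale (0 = range root,
#' 1200 = octave above). Population parameters are `c(mean, sd)` pairs;
#' draws from them are clipped to their natural support (SDs positive,
#' gamma in `[0, 0.9]`).
#'
#' Defaults emulate the qualitative geometry reported for human
#' cohorts: singing noisier than whistling, habitual sung pitch low in
#' the stimulus range and habitual whistled pitch high in it, stronger
#' compression for singing, sung bias slightly flat and whistled
#' slightly sharp, and a per-note count-error probability totalling
#' 0.0074 so that about 3.6% of 5-note trials are excluded.
#'
#' @param n_participants cohort size (default 28).
#' @param p_female probability a participant is female, which selects
#'   the sung stimulus octave (root 220 vs 110 Hz).
#' @param habitual,motor_sd,bias,gamma,range_low,range_high per-modality
#'   population `c(mean, sd)` pairs (lists with elements `sing`,
#'   `whistle`), cents except `gamma` (unitless).
#' @param perceptual_sd population `c(mean, sd)` of the shared
#'   perceptual noise SD, cents.
#' @param production_sd population `c(mean, sd)` of the shared
#'   production (respiratory) noise SD, cents.
#' @param p_omit,p_duplicate,p_octave_error per-note event probabilities.
#' @param mbea_trials number of melodic-discrimination trials (default 90).
#' @param mbea_transpositions transposition sizes (cents) of the three
#'   equally sized discrimination sets, hardest last.
#' @param seed root seed for the cohort stream.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 28,
                          p_female = 20 / 28,
                          habitual = list(sing = c(150, 150), whistle = c(1050, 150)),
                          motor_sd = list(sing = c(60, 12), whistle = c(20, 6)),
                          perceptual_sd = c(45, 20),
                          production_sd = c(35, 18),
                          bias = list(sing = c(-20, 25), whistle = c(20, 25)),
                          gamma = list(sing = c(0.15, 0.05), whistle = c(0.06, 0.03)),
                          range_low = list(sing = c(-250, 150), whistle = c(-250, 150)),
                          range_high = list(sing = c(1450, 150), whistle = c(1450, 150)),
                          p_omit = 0.0037, p_duplicate = 0.0037, p_octave_error = 0.001,
                          mbea_trials = 90, mbea_transpositions = c(300, 200, 100),
                          seed = 1) {
  pair_ok <- function(p) is.numeric(p) && length(p) == 2 && p[2] >= 0
  for (nm in c("habitual", "motor_sd", "bias", "gamma", "range_low", "range_high")) {
    v <- get(nm)
    stopifnot(is.list(v), all(c("sing", "whistle") %in% names(v)))
    stopifnot(pair_ok(v$sing), pair_ok(v$whistle))
  }
  stopifnot(
    pair_ok(perceptual_sd), pair_ok(production_sd), n_participants >= 1,
    p_omit >= 0, p_omit <= 1, p_duplicate >= 0, p_duplicate <= 1,
    p_octave_error >= 0, p_octave_error <= 1, p_female >= 0, p_female <= 1,
    mbea_trials >= 1, length(mbea_transpositions) >= 1
  )
  structure(
    list(
      n_participants = as.integer(n_participants), p_female = p_female,
      habitual = habitual, motor_sd = motor_sd, perceptual_sd = perceptual_sd,
      production_sd = production_sd,
      bias = bias, gamma = gamma, range_low = range_low, range_high = range_high,
      p_omit = p_omit, p_duplicate = p_duplicate, p_octave_error = p_octave_error,
      mbea_trials = as.integer(mbea_trials), mbea_transpositions = mbea_transpositions,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d participants; motor SD sing %g / whistle %g cents; gamma %g / %g; seed %d\n",
    x$n_participants, x$motor_sd$sing[1], x$motor_sd$whistle[1],
    x$gamma$sing[1], x$gamma$whistle[1], x$seed
  ))
  invisible(x)
}

#' A cohort with all between-modality differences removed
#'
#' Replaces every per-modality population parameter by the mean of its
#' sing and whistle values, yielding a generative model in which the
#' two modalities are exchangeable. Used for type-I-error calibration
#' of the modality tests.
#'
#' @param cohort a [cohort_config()].
#' @return a `cohort_config` with identical sing/whistle populations.
#' @export
null_cohort <- function(cohort = cohort_config()) {
  eq <- function(v) {
    m <- (v$sing + v$whistle) / 2
    list(sing = m, whistle = m)
  }
  cohort$habitual <- eq(cohort$habitual)
  cohort$motor_sd <- eq(cohort$motor_sd)
  cohort$bias <- eq(cohort$bias)
  cohort$gamma <- eq(cohort$gamma)
  cohort$range_low <- eq(cohort$range_low)
  cohort$range_high <- eq(cohort$range_high)
  cohort
}

clip <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

# Draw one participant's parameters; returns a 2-row tibble (one row per
# modality). Clipped-normal population draws.
draw_profile_rows <- function(cohort, participant_id, sex) {
  draw <- function(pair, lo = -Inf, hi = Inf) {
    clip(stats::rnorm(1, pair[1], pair[2]), lo, hi)
  }
  root <- c(
    sing = if (sex == "female") 220 else 110,
    whistle = 880
  )
  rows <- lapply(c("sing", "whistle"), function(m) {
    lo <- draw(cohort$range_low[[m]])
    hi <- clip(draw(cohort$range_high[[m]]), lo + 100, Inf) # keep range non-degenerate
    tibble::tibble(
      participant_id = participant_id, sex = sex, modality = m,
      root_hz = unname(root[m]),
      habitual_cents = draw(cohort$habitual[[m]]),
      range_low_cents = lo, range_high_cents = hi,
      motor_sd = draw(cohort$motor_sd[[m]], lo = 0),
      bias_cents = draw(cohort$bias[[m]]),
      gamma = draw(cohort$gamma[[m]], lo = 0, hi = 0.9)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$perceptual_sd <- clip(stats::rnorm(1, cohort$perceptual_sd[1], cohort$perceptual_sd[2]), 0, Inf)
  out$production_sd <- clip(stats::rnorm(1, cohort$production_sd[1], cohort$production_sd[2]), 0, Inf)
  out$p_omit <- cohort$p_omit
  out$p_duplicate <- cohort$p_duplicate
  out$p_octave_error <- cohort$p_octave_error
  out
}

#' Draw a performer profile from the cohort population
#'
#' @param cohort a [cohort_config()].
#' @param seed sub-stream seed (defaults to the cohort seed).
#' @param participant_id identifier for the drawn participant.
#' @return tibble with one row per modality carrying all generative
#'   parameters (habitual pitch, producible range, motor noise SD,
#'   bias, compression gamma, shared perceptual SD, event
#'   probabilities).
#' @export
draw_profile <- function(cohort, seed = cohort$seed, participant_id = "p01") {
  stopifnot(inherits(cohort, "cohort_config"))
  with_seed(seed, {
    sex <- if (stats::runif(1) < cohort$p_female) "female" else "male"
    draw_profile_rows(cohort, participant_id, sex)
  })
}

#' Draw the full cohort of performer profiles
#'
#' One sub-stream per participant, derived from the cohort seed, so the
#' cohort is reproducible and order-independent.
#'
#' @inheritParams draw_profile
#' @return tibble of profiles, two rows (modalities) per participant,
#'   plus a simulated melodic-discrimination score column
#'   `mbea_percent` (see [simulate_mbea()]).
#' @export
draw_cohort <- function(cohort, seed = cohort$seed) {
  stopifnot(inherits(cohort, "cohort_config"))
  profs <- lapply(seq_len(cohort$n_participants), function(i) {
    pid <- sprintf("p%02d", i)
    p <- draw_profile(cohort, seed = derive_seed(seed, paste0("profile", i)), participant_id = pid)
    p$mbea_percent <- simulate_mbea(p, cohort, seed = derive_seed(seed, paste0("mbea", i)))
    p
  })
  dplyr::bind_rows(profs)
}

# Vectorized generative core: produced cents for a vector of targets.
# Draws from the current RNG stream.
simulate_notes_cents <- function(targets, bias, gamma, habitual,
                                 perceptual_sd, production_sd, motor_sd,
                                 p_octave_error = 0) {
  n <- length(targets)
  out <- targets + bias + gamma * (habitual - targets) +
    stats::rnorm(n, 0, perceptual_sd) + stats::rnorm(n, 0, production_sd) +
    stats::rnorm(n, 0, motor_sd)
  if (any(p_octave_error > 0)) {
    jump <- stats::runif(n) < p_octave_error
    out[jump] <- out[jump] + sample(c(-1200, 1200), sum(jump), replace = TRUE)
  }
  out
}

#' Simulate one produced note
#'
#' Direct evaluation of the generative chain for a single target pitch:
#' perceptual noise, compression toward habitual pitch, constant bias,
#' motor noise, and a rare octave jump.
#'
#' @param target_cents target pitch, cents on the task scale.
#' @param profile one modality row of a profile tibble (see
#'   [draw_profile()]).
#' @param seed optional seed; if `NULL`, draws from the current RNG.
#' @return produced pitch in cents.
#' @export
#' @examples
#' p <- tibble::tibble(
#'   bias_cents = 0, gamma = 0.2, habitual_cents = 600,
#'   perceptual_sd = 0, production_sd = 0, motor_sd = 0, p_octave_error = 0
#' )
#' simulate_note(1100, p) # deterministic: 1000 cents
simulate_note <- function(target_cents, profile, seed = NULL) {
  stopifnot(nrow(profile) == 1, is.finite(target_cents))
  run <- function() {
    simulate_notes_cents(
      target_cents, profile$bias_cents, profile$gamma, profile$habitual_cents,
      profile$perceptual_sd, profile$production_sd, profile$motor_sd,
      profile$p_octave_error
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Apply omission/duplication to a produced-note table (columns must
# include trial_key and position). Each note is independently dropped
# with p_omit or repeated with p_duplicate (mutually exclusive).
apply_count_errors <- function(notes, p_omit, p_duplicate) {
  u <- stats::runif(nrow(notes))
  times <- rep(1L, nrow(notes))
  times[u < p_omit] <- 0L
  times[u >= p_omit & u < p_omit + p_duplicate] <- 2L
  notes$.times <- times
  out <- notes[rep(seq_len(nrow(notes)), times), , drop = FALSE]
  out$.times <- NULL
  out
}

#' Simulate one imitation trial
#'
#' Applies the generative note model to each note of a melody, converts
#' to Hz on the participant's task octave, and applies the per-note
#' omission/duplication process.
#'
#' @param degrees melody as integer scale degrees.
#' @param profile one modality row of a profile tibble.
#' @param melody_id identifier recorded in the output.
#' @param seed optional sub-stream seed.
#' @return tibble with one row per *produced* note: `participant_id`,
#'   `modality`, `melody_id`, `position` (index within the produced
#'   sequence), `target_cents` (aligned positionally; `NA` beyond the
#'   target length), `produced_hz`.
#' @export
simulate_trial <- function(degrees, profile, melody_id = "m01", seed = NULL) {
  stopifnot(nrow(profile) == 1)
  run <- function() {
    targets <- 100 * degrees
    cents <- simulate_notes_cents(
      targets, profile$bias_cents, profile$gamma, profile$habitual_cents,
      profile$perceptual_sd, profile$production_sd, profile$motor_sd,
      profile$p_octave_error
    )
    notes <- tibble::tibble(target_cents = targets, produced_cents = cents)
    notes <- apply_count_errors(notes, profile$p_omit, profile$p_duplicate)
    tibble::tibble(
      participant_id = profile$participant_id,
      modality = profile$modality,
      melody_id = melody_id,
      position = seq_len(nrow(notes)),
      target_cents = ifelse(seq_len(nrow(notes)) <= length(targets),
        100 * degrees[seq_len(nrow(notes))], NA_real_
      ),
      produced_hz = profile$root_hz * 2^(notes$produced_cents / 1200)
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a melodic-discrimination (perceptual ability) score
#'
#' Percent correct over same/different trials split into equally sized
#' sets of decreasing transposition size. The probability of a correct
#' response follows a logistic link on detectability,
#' `p = plogis(d')` with `d' = transposition / (2 * perceptual_sd)`:
#' chance (50%) when noise overwhelms the transposition, approaching
#' 100% as perceptual noise vanishes, and monotone decreasing in the
#' perceptual noise SD.
#'
#' @param profile profile tibble (any modality row; the perceptual SD
#'   is shared).
#' @param cohort a [cohort_config()] supplying trial counts and
#'   transposition sizes.
#' @param seed optional sub-stream seed.
#' @return percent correct in `[0, 100]`.
#' @export
simulate_mbea <- function(profile, cohort = cohort_config(), seed = NULL) {
  sd_p <- profile$perceptual_sd[1]
  sizes <- cohort$mbea_transpositions
  n_per <- cohort$mbea_trials %/% length(sizes)
  n_tot <- n_per * length(sizes)
  p <- stats::plogis(rep(sizes, each = n_per) / (2 * sd_p))
  run <- function() 100 * mean(stats::runif(n_tot) < p)
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Expected melodic-discrimination score for a given perceptual noise
#'
#' The noiseless-link expectation behind [simulate_mbea()]; useful for
#' checking monotonicity and limits.
#'
#' @param perceptual_sd perceptual noise SD, cents.
#' @param cohort a [cohort_config()].
#' @return expected percent correct.
#' @export
expected_mbea <- function(perceptual_sd, cohort = cohort_config()) {
  sapply(perceptual_sd, function(s) {
    100 * mean(stats::plogis(cohort$mbea_transpositions / (2 * s)))
  })
}

#' Simulate a full imitation study
#'
#' Draws a cohort, then has every participant imitate the sung melody
#' set by singing and the whistled set by whistling. Fully vectorized
#' over notes; reproducible under the seed via named sub-streams.
#'
#' @param cohort a [cohort_config()].
#' @param melodies named list with elements `sing` and `whistle`, each a
#'   tidy melody tibble from [compose_set()].
#' @param seed root seed (defaults to the cohort seed).
#' @return list with `trials` (one row per produced note:
#'   `participant_id`, `modality`, `melody_id`, `position`,
#'   `target_cents`, `produced_hz`) and `profiles` (ground-truth
#'   parameters plus `mbea_percent`).
#' @export
simulate_study <- function(cohort, melodies, seed = cohort$seed) {
  stopifnot(
    inherits(cohort, "cohort_config"),
    all(c("sing", "whistle") %in% names(melodies))
  )
  profiles <- draw_cohort(cohort, seed = derive_seed(seed, "cohort"))
  mel <- dplyr::bind_rows(
    dplyr::mutate(melodies$sing, modality = "sing"),
    dplyr::mutate(melodies$whistle, modality = "whistle")
  )
  mel$target_cents <- 100 * mel$degree

  # full participant x note grid
  grid <- dplyr::inner_join(profiles, mel, by = "modality", relationship = "many-to-many")
  grid <- grid[order(grid$participant_id, grid$modality, grid$melody_id, grid$position), ]

  trials <- with_seed(derive_seed(seed, "performance"), {
    produced <- simulate_notes_cents(
      grid$target_cents, grid$bias_cents, grid$gamma, grid$habitual_cents,
      grid$perceptual_sd, grid$production_sd, grid$motor_sd, grid$p_octave_error
    )
    notes <- tibble::tibble(
      participant_id = grid$participant_id, modality = grid$modality,
      melody_id = grid$melody_id, target_position = grid$position,
      target_cents = grid$target_cents, produced_cents = produced,
      root_hz = grid$root_hz
    )
    notes <- apply_count_errors(notes, cohort$p_omit, cohort$p_duplicate)
    notes <- dplyr::group_by(notes, participant_id, modality, melody_id)
    notes <- dplyr::mutate(notes, position = dplyr::row_number())
    notes <- dplyr::ungroup(notes)
    # positional target alignment: position i of the produced sequence
    # is paired with target note i (NA past the target length)
    n_notes <- max(mel$position)
    tgt <- mel[, c("modality", "melody_id", "position", "target_cents")]
    names(tgt)[4] <- "aligned_target_cents"
    notes <- dplyr::left_join(notes, tgt, by = c("modality", "melody_id", "position"))
    tibble::tibble(
      participant_id = notes$participant_id, modality = notes$modality,
      melody_id = notes$melody_id, position = notes$position,
      target_cents = notes$aligned_target_cents,
      produced_hz = notes$root_hz * 2^(notes$produced_cents / 1200)
    )
  })
  list(trials = trials, profiles = profiles)
}
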