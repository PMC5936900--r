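# Shared builders for tests. Everything is generated in code; no stored
# fixtures.

# A degenerate cohort: every population SD zero, so profiles equal the
# population means. Override any mean via the ... pairs.
fixed_cohort <- function(n_participants = 4,
                         habitual_sing = 150, habitual_whistle = 1050,
                         motor_sing = 0, motor_whistle = 0,
                         perceptual = 0, production = 0,
                         bias_sing = 0, bias_whistle = 0,
                         gamma_sing = 0, gamma_whistle = 0,
                         range_low = -10000, range_high = 10000,
                         p_omit = 0, p_duplicate = 0, p_octave_error = 0,
                         seed = 1) {
  cohort_config(
    n_participants = n_participants, p_female = 0.5,
    habitual = list(sing = c(habitual_sing, 0), whistle = c(habitual_whistle, 0)),
    motor_sd = list(sing = c(motor_sing, 0), whistle = c(motor_whistle, 0)),
    perceptual_sd = c(perceptual, 0),
    production_sd = c(production, 0),
    bias = list(sing = c(bias_sing, 0), whistle = c(bias_whistle, 0)),
    gamma = list(sing = c(gamma_sing, 0), whistle = c(gamma_whistle, 0)),
    range_low = list(sing = c(range_low, 0), whistle = c(range_low, 0)),
    range_high = list(sing = c(range_high, 0), whistle = c(range_high, 0)),
    p_omit = p_omit, p_duplicate = p_duplicate, p_octave_error = p_octave_error,
    seed = seed
  )
}

# One profile row with explicit generative parameters, for direct
# simulate_note / simulate_trial calls.
bare_profile <- function(participant_id = "p01", modality = "sing", root_hz = 110,
                         habitual_cents = 600, range_low_cents = -10000,
                         range_high_cents = 10000, motor_sd = 0, bias_cents = 0,
                         gamma = 0, perceptual_sd = 0, production_sd = 0,
                         p_omit = 0, p_duplicate = 0, p_octave_error = 0) {
  tibble::tibble(
    participant_id = participant_id, sex = "female", modality = modality,
    root_hz = root_hz, habitual_cents = habitual_cents,
    range_low_cents = range_low_cents, range_high_cents = range_high_cents,
    motor_sd = motor_sd, bias_cents = bias_cents, gamma = gamma,
    perceptual_sd = perceptual_sd, production_sd = production_sd,
    p_omit = p_omit, p_duplicate = p_duplicate, p_octave_error = p_octave_error
  )
}

# Build a well-formed trial table directly from target degrees and a
# produced-cents function, bypassing the stochastic simulator.
make_trials <- function(profile, melodies, produce = function(target_cents) target_cents) {
  rows <- lapply(names(melodies), function(id) {
    degrees <- melodies[[id]]
    tc <- 100 * degrees
    tibble::tibble(
      participant_id = profile$participant_id, modality = profile$modality,
      melody_id = id, position = seq_along(degrees), target_cents = tc,
      produced_hz = profile$root_hz * 2^(produce(tc) / 1200)
    )
  })
  dplyr::bind_rows(rows)
}

# Small melody list keyed by id.
toy_melodies <- function(n = 10, n_notes = 5, seed = 99) {
  cfg <- composition_config(n_melodies = n, n_notes = n_notes, seed = seed)
  set <- compose_set(cfg)
  split(set$degree, set$melody_id)
}
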