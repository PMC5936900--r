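test_that("a degenerate cohort yields profiles equal to the population means", {
  ch <- fixed_cohort(
    habitual_sing = 200, habitual_whistle = 900, motor_sing = 50,
    motor_whistle = 25, perceptual = 40, production = 30,
    bias_sing = -15, bias_whistle = 10, gamma_sing = 0.2, gamma_whistle = 0.1,
    range_low = -100, range_high = 1300
  )
  p <- draw_profile(ch, seed = 5)
  expect_equal(nrow(p), 2)
  sing <- p[p$modality == "sing", ]
  expect_equal(sing$habitual_cents, 200)
  expect_equal(sing$motor_sd, 50)
  expect_equal(sing$perceptual_sd, 40)
  expect_equal(sing$production_sd, 30)
  expect_equal(sing$bias_cents, -15)
  expect_equal(sing$gamma, 0.2)
  expect_equal(p[p$modality == "whistle", ]$habitual_cents, 900)
  expect_identical(draw_profile(ch, seed = 5), draw_profile(ch, seed = 5))
})

test_that("profile draws concentrate around the configured population means", {
  ch <- cohort_config(seed = 1)
  draws <- dplyr::bind_rows(lapply(1:400, function(i) {
    draw_profile(ch, seed = derive_seed(1, paste0("clt", i)))
  }))
  sing <- draws[draws$modality == "sing", ]
  # CLT bounds: |mean - mu| < 4 * sd/sqrt(n) (clipping effects negligible here)
  expect_lt(abs(mean(sing$habitual_cents) - 150), 4 * 150 / 20)
  expect_lt(abs(mean(sing$motor_sd) - 60), 4 * 12 / 20)
  expect_lt(abs(mean(sing$gamma) - 0.15), 4 * 0.05 / 20)
  expect_lt(abs(mean(sing$perceptual_sd) - 45), 4 * 20 / 20 + 1) # +1 for clip at 8
  # the intended modality asymmetries hold in expectation
  whis <- draws[draws$modality == "whistle", ]
  expect_gt(mean(sing$motor_sd), mean(whis$motor_sd))
  expect_gt(mean(sing$gamma), mean(whis$gamma))
  expect_lt(mean(sing$habitual_cents), mean(whis$habitual_cents))
})

test_that("the generative note model evaluates its stated formula", {
  p <- bare_profile(gamma = 0.2, habitual_cents = 600)
  # zero noise, zero bias: target + 0.2 * (600 - 1100) = 1000
  expect_equal(simulate_note(1100, p), 1000)
  # identity when gamma = 0 and all noise off
  p0 <- bare_profile()
  expect_equal(simulate_note(730, p0), 730)
  # gamma -> 1 limit pulls output to the habitual pitch
  p9 <- bare_profile(gamma = 0.999, habitual_cents = 600)
  expect_lt(abs(simulate_note(1100, p9) - 600), 1)
  # constant bias shifts one-to-one
  pb <- bare_profile(bias_cents = 35)
  expect_equal(simulate_note(400, pb), 435)
})

test_that("omission and duplication rates match their probabilities", {
  mel <- list(m1 = c(0, 2, 4, 5, 7))
  p_omit <- 0.2
  p <- bare_profile(p_omit = p_omit)
  counts <- withr::with_seed(11, {
    vapply(1:500, function(i) nrow(simulate_trial(mel$m1, p)), numeric(1))
  })
  # produced notes ~ Binomial(2500, 1 - p_omit)
  n_prod <- sum(counts)
  expected <- 2500 * (1 - p_omit)
  expect_lt(abs(n_prod - expected), 4 * sqrt(2500 * p_omit * (1 - p_omit)))
  # zero probabilities: always the full note count
  p0 <- bare_profile()
  expect_true(all(vapply(1:50, function(i) {
    nrow(simulate_trial(mel$m1, p0, seed = i))
  }, numeric(1)) == 5))
  expect_identical(
    simulate_trial(mel$m1, p, seed = 3),
    simulate_trial(mel$m1, p, seed = 3)
  )
})

test_that("duplicated notes repeat and extend the produced sequence", {
  p <- bare_profile(p_duplicate = 1) # every note duplicated
  tr <- simulate_trial(c(0, 2), p, seed = 1)
  expect_equal(nrow(tr), 4)
  expect_equal(tr$position, 1:4)
  # positional target alignment: NA beyond the target length
  expect_true(all(is.na(tr$target_cents[3:4])))
})

test_that("melodic discrimination scores fall with perceptual noise", {
  ch <- cohort_config()
  # limits of the link
  sharp <- bare_profile(perceptual_sd = 1e-9)
  expect_equal(simulate_mbea(sharp, ch, seed = 1), 100)
  dull <- bare_profile(perceptual_sd = 1e9)
  score <- mean(vapply(1:40, function(i) simulate_mbea(dull, ch, seed = i), numeric(1)))
  expect_lt(abs(score - 50), 5) # binomial noise around chance
  # monotone decreasing expectation over a noise grid
  grid <- expected_mbea(c(10, 20, 40, 80, 160), ch)
  expect_true(all(diff(grid) < 0))
  expect_true(all(grid >= 50 & grid <= 100))
})

test_that("a simulated study has the designed layout and is reproducible", {
  ch <- cohort_config(n_participants = 6, seed = 21)
  mel <- list(
    sing = compose_set(composition_config(n_melodies = 45, seed = 1)),
    whistle = compose_set(composition_config(n_melodies = 45, seed = 2))
  )
  sim <- simulate_study(ch, mel)
  trials <- dplyr::distinct(sim$trials[, c("participant_id", "modality", "melody_id")])
  expect_equal(nrow(trials), 6 * 2 * 45) # 90 trials per participant
  expect_equal(sort(unique(sim$trials$modality)), c("sing", "whistle"))
  expect_equal(
    names(sim$trials),
    c("participant_id", "modality", "melody_id", "position", "target_cents", "produced_hz")
  )
  expect_true(all(sim$trials$produced_hz > 0))
  expect_equal(nrow(sim$profiles), 12)
  expect_true(all(sim$profiles$range_low_cents < sim$profiles$range_high_cents))
  sim2 <- simulate_study(ch, mel)
  expect_identical(sim$trials, sim2$trials)
  expect_identical(sim$profiles, sim2$profiles)
})

test_that("with no bias or compression the mean signed error is zero", {
  ch <- fixed_cohort(
    n_participants = 6, motor_sing = 60, motor_whistle = 20,
    perceptual = 45, production = 35, seed = 31
  )
  mel <- list(
    sing = compose_set(composition_config(seed = 3)),
    whistle = compose_set(composition_config(seed = 4))
  )
  sim <- simulate_study(ch, mel)
  errs <- note_errors(filter_trials(sim$trials, sim$profiles)$kept, sim$profiles)
  # per-note error SD is sqrt(45^2+35^2+60^2) ~ 83; 3-SE bound on the mean
  n <- nrow(errs)
  expect_lt(abs(mean(errs$error_cents)), 3 * 83 / sqrt(n))
})

test_that("regressing error on target pitch recovers minus gamma", {
  ch <- fixed_cohort(
    n_participants = 8, gamma_sing = 0.25, gamma_whistle = 0.1,
    perceptual = 30, production = 20, motor_sing = 40, motor_whistle = 15,
    seed = 41
  )
  mel <- list(
    sing = compose_set(composition_config(seed = 5)),
    whistle = compose_set(composition_config(seed = 6))
  )
  sim <- simulate_study(ch, mel)
  errs <- note_errors(filter_trials(sim$trials, sim$profiles)$kept, sim$profiles)
  for (m in c("sing", "whistle")) {
    e <- errs[errs$modality == m, ]
    fit <- stats::lm(error_cents ~ target_cents, data = e)
    slope <- stats::coef(fit)[2]
    se <- summary(fit)$coefficients[2, 2]
    truth <- if (m == "sing") -0.25 else -0.1
    expect_lt(abs(slope - truth), 4 * se)
  }
})

test_that("shared-stage variance drives the cross-modality imprecision correlation", {
  mel <- list(
    sing = compose_set(composition_config(seed = 7)),
    whistle = compose_set(composition_config(seed = 8))
  )
  corr_for <- function(shared_sd_spread, motor_spread, seed) {
    ch <- cohort_config(
      n_participants = 24,
      perceptual_sd = c(45, shared_sd_spread),
      production_sd = c(35, shared_sd_spread),
      motor_sd = list(sing = c(60, motor_spread), whistle = c(20, motor_spread)),
      p_omit = 0, p_duplicate = 0, p_octave_error = 0,
      seed = seed
    )
    sim <- simulate_study(ch, mel)
    sc <- score_participants(filter_trials(sim$trials, sim$profiles), sim$profiles)
    wide <- tidyr::pivot_wider(sc[, c("participant_id", "modality", "note_imprecision")],
      names_from = "modality", values_from = "note_imprecision"
    )
    stats::cor(wide$sing, wide$whistle)
  }
  shared_dominant <- mean(vapply(1:3, function(i) corr_for(25, 2, 100 + i), numeric(1)))
  motor_dominant <- mean(vapply(1:3, function(i) corr_for(2, 18, 200 + i), numeric(1)))
  expect_gt(shared_dominant, motor_dominant)
  expect_gt(shared_dominant, 0.5)
})
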