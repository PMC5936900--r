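# Small score tables for model tests, built at the score level.
score_fixture <- function(n = 20, gap = -30, mbea_slope = 0, resid_sd = 10, seed = 1) {
  withr::with_seed(seed, {
    pid <- sprintf("p%02d", 1:n)
    intercept <- stats::rnorm(n, 100, 25)
    mbea <- stats::rnorm(n, 86, 9)
    tibble::tibble(
      participant_id = rep(pid, each = 2),
      modality = rep(c("sing", "whistle"), n),
      mbea_percent = rep(mbea, each = 2),
      note_imprecision = rep(intercept, each = 2) +
        ifelse(modality == "whistle", gap, 0) +
        mbea_slope * (rep(mbea, each = 2) - 86) +
        stats::rnorm(2 * n, 0, resid_sd)
    )
  })
}

test_that("the standardized binary contrast equals the between-condition difference", {
  sc <- score_fixture(n = 16, gap = -25, seed = 2)
  est <- standardized_estimates(sc, "note_imprecision", effects = "modality")$modality
  raw_diff <- mean(sc$note_imprecision[sc$modality == "whistle"]) -
    mean(sc$note_imprecision[sc$modality == "sing"])
  expect_equal(est, raw_diff, tolerance = 1e-6)
})

test_that("a standardized continuous estimate is 2 SD times the raw slope", {
  sc <- score_fixture(n = 18, gap = 0, mbea_slope = -2, seed = 3)
  est <- standardized_estimates(sc, "note_imprecision", effects = "mbea_percent")$mbea_percent
  raw <- lme4::fixef(lme4::lmer(
    note_imprecision ~ mbea_percent + (1 | participant_id),
    data = sc, REML = TRUE
  ))["mbea_percent"]
  expect_equal(est, unname(raw) * 2 * stats::sd(sc$mbea_percent), tolerance = 1e-6)
  # standardizing an already standardized input changes nothing
  sdat <- standardize_inputs(sc, "mbea_percent")
  est2 <- standardized_estimates(sdat, "note_imprecision", effects = "mbea_percent")$mbea_percent
  expect_equal(est2, est, tolerance = 1e-6)
})

test_that("standardization rejects degenerate predictors", {
  sc <- score_fixture(n = 10)
  sc$flat <- 1
  expect_error(standardize_inputs(sc, "flat"), "zero-variance")
  sc$many <- sample(c("a", "b", "c"), nrow(sc), replace = TRUE)
  expect_error(standardize_inputs(sc, "many"), "2 levels")
})

test_that("nested KR tests report the modality and perceptual effects", {
  sc <- score_fixture(n = 20, gap = -40, mbea_slope = -3, resid_sd = 8, seed = 4)
  res <- fit_nested_lmm(sc, "note_imprecision")
  expect_s3_class(res, "model_result")
  expect_equal(res$effect, c("modality", "mbea_percent"))
  expect_equal(res$df1, c(1, 1))
  expect_true(all(res$df_method == "Kenward-Roger"))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_lt(res$p[res$effect == "modality"], 0.01) # designed-in large gap
  expect_lt(abs(res$std_estimate[res$effect == "modality"] - (-40)), 12)
})

test_that("an effect absent from the data yields a near-zero estimate and large p", {
  # modality carries no information: whistle rows copy sing rows exactly
  withr::with_seed(5, {
    n <- 16
    y <- stats::rnorm(n, 100, 20)
    sc <- tibble::tibble(
      participant_id = rep(sprintf("p%02d", 1:n), each = 2),
      modality = rep(c("sing", "whistle"), n),
      mbea_percent = rep(stats::rnorm(n, 86, 9), each = 2),
      note_imprecision = rep(y, each = 2)
    )
  })
  res <- fit_nested_lmm(sc, "note_imprecision")
  mod <- res[res$effect == "modality", ]
  expect_lt(abs(mod$std_estimate), 1e-8)
  expect_true(is.na(mod$F) || mod$F < 1e-6 || mod$p > 0.99)
})

test_that("the cluster bootstrap is seeded, degenerate-safe and covers the estimate", {
  # degenerate: scores are an exact function of modality
  det <- tibble::tibble(
    participant_id = rep(sprintf("p%02d", 1:8), each = 2),
    modality = rep(c("sing", "whistle"), 8),
    mbea_percent = rep(seq(70, 98, length.out = 8), each = 2),
    note_imprecision = ifelse(modality == "whistle", 60, 90)
  )
  ci <- bootstrap_ci(det, "note_imprecision", "modality", n_boot = 50, seed = 9)
  expect_equal(ci$ci_low, -30)
  expect_equal(ci$ci_high, -30)
  # stochastic: reproducible, and the percentile interval brackets the estimate
  sc <- score_fixture(n = 14, gap = -30, seed = 6)
  ci1 <- bootstrap_ci(sc, "note_imprecision", "modality", n_boot = 99, seed = 3)
  ci2 <- bootstrap_ci(sc, "note_imprecision", "modality", n_boot = 99, seed = 3)
  expect_identical(ci1, ci2)
  est <- standardized_estimates(sc, "note_imprecision")$modality
  expect_lte(ci1$ci_low, est)
  expect_gte(ci1$ci_high, est)
  expect_error(bootstrap_ci(sc[1:6, ], "note_imprecision", "modality"), ">= 5")
})

test_that("bootstrap intervals tighten as the cohort grows", {
  width <- function(n, seed) {
    sc <- score_fixture(n = n, gap = -30, seed = seed)
    ci <- bootstrap_ci(sc, "note_imprecision", "modality", n_boot = 99, seed = 11)
    ci$ci_high - ci$ci_low
  }
  w_small <- mean(vapply(1:3, function(s) width(8, s), numeric(1)))
  w_large <- mean(vapply(1:3, function(s) width(32, s), numeric(1)))
  expect_lt(w_large, w_small)
})

test_that("partial correlation matches the textbook recursion formula", {
  expect_equal(partial_correlation(1:10, 1:10, controls = stats::rnorm(10))$r_squared, 1)
  withr::with_seed(7, {
    z <- stats::rnorm(400)
    x <- 0.8 * z + stats::rnorm(400)
    y <- 0.8 * z + stats::rnorm(400)
    # x and y are independent given z
    res <- partial_correlation(x, y, z)
    expect_lt(abs(res$r), 0.15)
    expect_equal(res$df, 397)
    # oracle: r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))
    r_xy <- stats::cor(x, y)
    r_xz <- stats::cor(x, z)
    r_yz <- stats::cor(y, z)
    oracle <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
    expect_equal(res$r, oracle, tolerance = 1e-10)
  })
})

test_that("partial correlation rejects collinear controls and tiny samples", {
  withr::with_seed(8, {
    x <- stats::rnorm(20)
    y <- stats::rnorm(20)
    z <- stats::rnorm(20)
    expect_error(partial_correlation(x, y, cbind(z, 2 * z)), "collinear")
    expect_error(partial_correlation(x[1:3], y[1:3], z[1:3]), "observations")
  })
})

test_that("the post-hoc model recovers compression signatures and nulls", {
  mel <- list(
    sing = compose_set(composition_config(seed = 11)),
    whistle = compose_set(composition_config(seed = 12))
  )
  # compression on: negative slope, positive interaction (sing steeper)
  ch <- fixed_cohort(
    n_participants = 10, gamma_sing = 0.25, gamma_whistle = 0.08,
    perceptual = 30, production = 20, motor_sing = 40, motor_whistle = 15, seed = 71
  )
  sim <- simulate_study(ch, mel)
  errs <- note_errors(filter_trials(sim$trials, sim$profiles)$kept, sim$profiles)
  res <- posthoc_target_pitch_model(errs)
  expect_setequal(res$effect, c("modality", "target_cents", "modality:target_cents"))
  expect_lt(res$std_estimate[res$effect == "target_cents"], 0)
  expect_gt(res$std_estimate[res$effect == "modality:target_cents"], 0)
  expect_lt(res$p[res$effect == "target_cents"], 0.01)
  # compression off: slope indistinguishable from zero
  ch0 <- fixed_cohort(
    n_participants = 10, perceptual = 30, production = 20,
    motor_sing = 40, motor_whistle = 15, seed = 72
  )
  sim0 <- simulate_study(ch0, mel)
  errs0 <- note_errors(filter_trials(sim0$trials, sim0$profiles)$kept, sim0$profiles)
  res0 <- posthoc_target_pitch_model(errs0)
  expect_lt(abs(res0$std_estimate[res0$effect == "target_cents"]), 20)
  expect_gt(res0$p[res0$effect == "target_cents"], 0.01)
})
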