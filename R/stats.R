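#' 2-SD standardization of model inputs
#'
#' Continuous predictors are centred and divided by twice their sample
#' SD, so an estimated coefficient is the expected outcome difference
#' between a predictor 1 SD below and 1 SD above its mean. Binary
#' predictors (two-level factors or two-valued columns) are coded
#' `-0.5 / +0.5`, which makes their coefficient exactly the estimated
#' between-condition difference and puts them on the same footing as
#' the 2-SD-scaled continuous inputs.
#'
#' @param data data frame.
#' @param predictors column names to standardize.
#' @return `data` with the named columns replaced by standardized
#'   numeric versions; the level mapped to `+0.5` for each binary
#'   predictor is recorded in the `"binary_levels"` attribute (the
#'   second sorted level, e.g. `whistle` in a sing/whistle contrast).
#' @export
standardize_inputs <- function(data, predictors) {
  binary_levels <- list()
  for (p in predictors) {
    x <- data[[p]]
    if (is.null(x)) stop("predictor not found: ", p)
    ux <- sort(unique(stats::na.omit(as.character(x))))
    if (is.factor(x) || is.character(x) || length(unique(stats::na.omit(x))) == 2) {
      if (length(ux) != 2) stop("categorical predictor ", p, " must have exactly 2 levels")
      data[[p]] <- ifelse(as.character(x) == ux[2], 0.5, -0.5)
      binary_levels[[p]] <- ux[2]
    } else {
      s <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0) stop("zero-variance predictor: ", p)
      data[[p]] <- (x - mean(x, na.rm = TRUE)) / (2 * s)
    }
  }
  attr(data, "binary_levels") <- binary_levels
  data
}

# Fit a random-intercept LMM, tolerating degenerate (zero-variance)
# data by falling back to a fixed-effects lm. Returns list(fit, engine).
fit_ri_model <- function(formula, data, reml = TRUE) {
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(formula, data = data, REML = reml)
    )),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    return(list(fit = fit, engine = "lmer"))
  }
  # strip the random-intercept term and fall back to lm (degenerate data)
  f <- stats::as.formula(
    paste(deparse(formula[[2]]), "~", gsub("\\+?\\s*\\(1 \\| [^)]+\\)", "", deparse(formula[[3]])))
  )
  list(fit = stats::lm(f, data = data), engine = "lm")
}

#' Nested mixed-model tests for the imitation scores
#'
#' Fits `outcome ~ modality + mbea_percent + (1 | participant_id)` (or
#' the supplied fixed effects) and tests each fixed effect by a nested
#' model comparison against the fit with that effect dropped, with
#' degrees of freedom and p-values from the Kenward-Roger
#' approximation. Standardized estimates come from refitting the full
#' model with inputs standardized by [standardize_inputs()]; for the
#' modality contrast the estimate is whistle minus sing.
#'
#' @param scores a long score table (one row per participant x
#'   modality), e.g. from [score_participants()].
#' @param outcome outcome column name (one of the four score types).
#' @param effects fixed-effect column names to include in the model.
#' @param test_effects effects to test by nested comparison (default:
#'   all of `effects`).
#' @param group grouping column for the random intercept.
#' @return a `model_result` tibble, one row per tested effect: `F`,
#'   `df1`, `df2`, `p`, `std_estimate`, `df_method`, `engine`. Bootstrap
#'   CIs are added separately by [bootstrap_ci()].
#' @export
fit_nested_lmm <- function(scores, outcome, effects = c("modality", "mbea_percent"),
                           test_effects = effects, group = "participant_id") {
  stopifnot(
    outcome %in% names(scores), all(effects %in% names(scores)),
    all(test_effects %in% effects)
  )
  dat <- scores[stats::complete.cases(scores[, c(outcome, effects, group)]), ]
  if (length(unique(dat[[group]])) < 2) stop("need >= 2 participants")
  rhs <- paste(effects, collapse = " + ")
  full_f <- stats::as.formula(paste(outcome, "~", rhs, "+ (1 |", group, ")"))
  full <- fit_ri_model(full_f, dat)
  est <- standardized_estimates(dat, outcome, effects, group)

  rows <- lapply(test_effects, function(e) {
    red_rhs <- paste(setdiff(effects, e), collapse = " + ")
    if (red_rhs == "") red_rhs <- "1"
    red_f <- stats::as.formula(paste(outcome, "~", red_rhs, "+ (1 |", group, ")"))
    if (full$engine == "lmer") {
      red <- fit_ri_model(red_f, dat)
      if (red$engine == "lmer") {
        kr <- tryCatch(pbkrtest::KRmodcomp(full$fit, red$fit), error = function(e) NULL)
        if (!is.null(kr)) {
          s <- kr$stats
          return(tibble::tibble(
            outcome = outcome, effect = e, F = s$Fstat, df1 = s$ndf, df2 = s$ddf,
            p = s$p.value, std_estimate = est[[e]],
            df_method = "Kenward-Roger", engine = "lmer"
          ))
        }
      }
    }
    # degenerate-data fallback: classical F from nested least squares
    f0 <- stats::as.formula(paste(outcome, "~", rhs))
    f1 <- stats::as.formula(paste(outcome, "~", red_rhs))
    a <- stats::anova(stats::lm(f1, dat), stats::lm(f0, dat))
    tibble::tibble(
      outcome = outcome, effect = e, F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2],
      p = a$`Pr(>F)`[2], std_estimate = est[[e]],
      df_method = "classical", engine = "lm"
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("model_result", class(out))
  out
}

#' Standardized fixed-effect estimates
#'
#' Refits the random-intercept model with inputs standardized (2-SD
#' scaling for continuous, `-0.5/+0.5` for binary predictors) and
#' returns the fixed-effect estimates. Cheap: a single model fit, no
#' df machinery — useful inside replicate loops.
#'
#' @inheritParams fit_nested_lmm
#' @return named list of standardized estimates, one per effect.
#' @export
standardized_estimates <- function(scores, outcome, effects = c("modality", "mbea_percent"),
                                   group = "participant_id") {
  dat <- scores[stats::complete.cases(scores[, c(outcome, effects, group)]), ]
  sdat <- standardize_inputs(dat, effects)
  f <- stats::as.formula(paste(
    outcome, "~", paste(effects, collapse = " + "), "+ (1 |", group, ")"
  ))
  m <- fit_ri_model(f, sdat)
  b <- if (m$engine == "lmer") lme4::fixef(m$fit) else stats::coef(m$fit)
  out <- as.list(b[effects])
  names(out) <- effects
  out
}

#' Cluster bootstrap CI for a standardized estimate
#'
#' Resamples participants (whole clusters) with replacement, refits the
#' standardized model on each resample, and returns the percentile
#' interval of the standardized estimate. Row-level resampling would
#' break the random-intercept correlation structure, so clusters are
#' the resampling unit.
#'
#' @inheritParams fit_nested_lmm
#' @param effect the single effect whose estimate is bootstrapped.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed seed for the resampling stream.
#' @param level confidence level (default 0.95).
#' @return tibble with `ci_low`, `ci_high`, `n_boot`, `n_failed`.
#' @export
bootstrap_ci <- function(scores, outcome, effect, effects = c("modality", "mbea_percent"),
                         group = "participant_id", n_boot = 1000, seed = 1, level = 0.95) {
  dat <- scores[stats::complete.cases(scores[, c(outcome, effects, group)]), ]
  ids <- unique(dat[[group]])
  if (length(ids) < 5) stop("need >= 5 participants to bootstrap")
  by_id <- split(dat, dat[[group]])
  est <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample(ids, length(ids), replace = TRUE)
      res <- dplyr::bind_rows(lapply(seq_along(pick), function(j) {
        d <- by_id[[as.character(pick[j])]]
        d[[group]] <- paste0("bs", j) # resampled clusters are distinct units
        d
      }))
      tryCatch(standardized_estimates(res, outcome, effects, group)[[effect]],
        error = function(e) NA_real_
      )
    }, numeric(1))
  })
  ok <- est[is.finite(est)]
  if (length(ok) == 0) stop("all bootstrap refits failed")
  alpha <- (1 - level) / 2
  qs <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(
    outcome = outcome, effect = effect, ci_low = qs[1], ci_high = qs[2],
    n_boot = n_boot, n_failed = n_boot - length(ok)
  )
}

#' Partial correlation controlling for covariates
#'
#' Correlates the residuals of `x` and `y` after linear regression of
#' each on the controls; the p-value is the t-test on the residual
#' correlation with `n - n_controls - 2` degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param controls numeric vector, matrix or data frame of control
#'   covariates (may be `NULL` for a plain correlation).
#' @return tibble with `r`, `r_squared`, `p`, `n`, `df`,
#'   `n_controls`.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(controls)) {
    z <- matrix(numeric(0), nrow = length(x), ncol = 0)
  } else {
    z <- as.matrix(as.data.frame(controls))
    stopifnot(nrow(z) == length(x))
  }
  keep <- stats::complete.cases(cbind(x, y, z))
  x <- x[keep]
  y <- y[keep]
  z <- z[keep, , drop = FALSE]
  n <- length(x)
  k <- ncol(z)
  if (n <= k + 2) stop("need n > n_controls + 2 observations")
  if (k > 0) {
    if (qr(cbind(1, z))$rank < k + 1) stop("collinear controls")
    rx <- stats::lm.fit(cbind(1, z), x)$residuals
    ry <- stats::lm.fit(cbind(1, z), y)$residuals
  } else {
    rx <- x - mean(x)
    ry <- y - mean(y)
  }
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  t <- r * sqrt(df / (1 - r^2))
  tibble::tibble(
    r = r, r_squared = r^2, p = 2 * stats::pt(-abs(t), df),
    n = n, df = df, n_controls = k
  )
}

#' Post-hoc model: inaccuracy as a function of target pitch
#'
#' Aggregates note errors to the mean error per participant, modality
#' and target pitch class, then fits
#' `error ~ modality * target_cents + (1 | participant)` with
#' Kenward-Roger tests of the modality effect, the target-pitch slope
#' and their interaction (main effects tested in the additive model,
#' the interaction against it). Under the compression account the
#' slope is negative (high targets imitated flat, low targets sharp)
#' and the interaction positive when compression is stronger for
#' singing.
#'
#' @param errors note-error table from [note_errors()].
#' @return a `model_result` tibble with rows for `modality`,
#'   `target_cents` and `modality:target_cents`. Standardized
#'   estimates use the 2-SD convention (binary modality as whistle
#'   minus sing).
#' @export
posthoc_target_pitch_model <- function(errors) {
  agg <- dplyr::summarise(
    dplyr::group_by(errors, participant_id, modality, pitch_class),
    mean_error = mean(error_cents), .groups = "drop"
  )
  agg$target_cents <- 100 * agg$pitch_class

  sdat <- standardize_inputs(agg, c("modality", "target_cents"))
  full_s <- fit_ri_model(mean_error ~ modality * target_cents + (1 | participant_id), sdat)
  b <- if (full_s$engine == "lmer") lme4::fixef(full_s$fit) else stats::coef(full_s$fit)
  est <- c(
    modality = unname(b["modality"]),
    target_cents = unname(b["target_cents"]),
    `modality:target_cents` = unname(b["modality:target_cents"])
  )

  full <- fit_ri_model(mean_error ~ modality * target_cents + (1 | participant_id), agg)
  addv <- fit_ri_model(mean_error ~ modality + target_cents + (1 | participant_id), agg)
  cmp <- list(
    modality = list(
      big = addv,
      small = fit_ri_model(mean_error ~ target_cents + (1 | participant_id), agg)
    ),
    target_cents = list(
      big = addv,
      small = fit_ri_model(mean_error ~ modality + (1 | participant_id), agg)
    ),
    `modality:target_cents` = list(big = full, small = addv)
  )
  rows <- lapply(names(cmp), function(e) {
    pair <- cmp[[e]]
    if (pair$big$engine == "lmer" && pair$small$engine == "lmer") {
      kr <- tryCatch(pbkrtest::KRmodcomp(pair$big$fit, pair$small$fit), error = function(x) NULL)
      if (!is.null(kr)) {
        s <- kr$stats
        return(tibble::tibble(
          outcome = "note_error", effect = e, F = s$Fstat, df1 = s$ndf, df2 = s$ddf,
          p = s$p.value, std_estimate = unname(est[e]),
          df_method = "Kenward-Roger", engine = "lmer"
        ))
      }
    }
    a <- stats::anova(
      stats::lm(stats::formula(stats::terms(stats::as.formula(
        "mean_error ~ modality * target_cents"
      ))), agg)
    )
    tibble::tibble(
      outcome = "note_error", effect = e, F = NA_real_, df1 = NA_real_, df2 = NA_real_,
      p = NA_real_, std_estimate = unname(est[e]), df_method = "classical", engine = "lm"
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("model_result", class(out))
  out
}

utils::globalVariables(c("mean_error"))
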