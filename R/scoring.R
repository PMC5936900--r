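#' Convert frequency to cents relative to a reference
#'
#' `cents = log2(f / ref) * 1200`: 100 cents is one equal-temperament
#' semitone, 1200 cents one octave. In the imitation task the reference
#' is the root (lowest scale degree) of the stimulus range.
#'
#' @param f frequency in Hz (vectorized).
#' @param ref reference frequency in Hz.
#' @return pitch in cents relative to `ref`.
#' @export
#' @examples
#' hz_to_cents(220, 110) # 1200
#' hz_to_cents(110 * 2^(1 / 12), 110) # 100
hz_to_cents <- function(f, ref) {
  if (any(!is.finite(f) | f <= 0)) stop("frequencies must be positive and finite")
  if (any(!is.finite(ref) | ref <= 0)) stop("reference must be positive and finite")
  log2(f / ref) * 1200
}

#' Exclusion filters for imitation trials
#'
#' Applies the two structural exclusion rules before scoring:
#' trials whose produced note count differs from the target note count
#' (the positions of omitted or duplicated notes cannot be determined),
#' and trials whose *target* melody contains any note outside the
#' participant's producible range for that modality (such responses
#' reflect range limits, not imitation ability).
#'
#' @param trials tidy trial table: `participant_id`, `modality`,
#'   `melody_id`, `position`, `target_cents`, `produced_hz` (one row per
#'   produced note). Target notes for range checking are taken from the
#'   trial rows' `target_cents`; supply `targets` if produced counts may
#'   differ from target counts.
#' @param profiles profile table with `participant_id`, `modality`,
#'   `range_low_cents`, `range_high_cents` (cents on the task scale).
#' @param n_notes target note count per melody (default 5).
#' @param targets optional melody table (`modality`, `melody_id`,
#'   `position`, `target_cents`) defining the target notes; defaults to
#'   the distinct target rows found in `trials`.
#' @return list with `kept` (trial rows passing both filters) and
#'   `excluded` (one row per excluded trial: ids plus a
#'   machine-readable `reason`, one of `"too_few_notes"`,
#'   `"too_many_notes"`, `"target_out_of_range"`).
#' @export
filter_trials <- function(trials, profiles, n_notes = 5, targets = NULL) {
  need <- c("participant_id", "modality", "melody_id", "position", "produced_hz")
  stopifnot(all(need %in% names(trials)))
  if (!all(c("range_low_cents", "range_high_cents") %in% names(profiles))) {
    stop("profiles must carry range_low_cents and range_high_cents")
  }
  counts <- dplyr::count(trials, participant_id, modality, melody_id, name = "n_produced")

  if (is.null(targets)) {
    targets <- dplyr::distinct(
      trials[!is.na(trials$target_cents), ],
      modality, melody_id, position, target_cents
    )
  }
  rng <- dplyr::distinct(
    profiles[, c("participant_id", "modality", "range_low_cents", "range_high_cents")]
  )
  miss <- dplyr::anti_join(
    dplyr::distinct(trials[, c("participant_id", "modality")]), rng,
    by = c("participant_id", "modality")
  )
  if (nrow(miss) > 0) {
    stop(
      "missing producible range for: ",
      paste(miss$participant_id, miss$modality, sep = "/", collapse = ", ")
    )
  }
  # a trial is out of range if ANY target note of its melody lies outside
  # the participant's producible range in that modality
  tr_rng <- dplyr::inner_join(
    dplyr::distinct(trials[, c("participant_id", "modality", "melody_id")]),
    targets,
    by = c("modality", "melody_id"), relationship = "many-to-many"
  )
  tr_rng <- dplyr::inner_join(tr_rng, rng, by = c("participant_id", "modality"))
  oor <- dplyr::summarise(
    dplyr::group_by(tr_rng, participant_id, modality, melody_id),
    out_of_range = any(target_cents < range_low_cents | target_cents > range_high_cents),
    .groups = "drop"
  )

  status <- dplyr::left_join(counts, oor, by = c("participant_id", "modality", "melody_id"))
  status$out_of_range[is.na(status$out_of_range)] <- FALSE
  status$reason <- dplyr::case_when(
    status$n_produced < n_notes ~ "too_few_notes",
    status$n_produced > n_notes ~ "too_many_notes",
    status$out_of_range ~ "target_out_of_range",
    TRUE ~ NA_character_
  )
  excluded <- status[!is.na(status$reason), c("participant_id", "modality", "melody_id", "n_produced", "reason")]
  kept <- dplyr::anti_join(trials, excluded, by = c("participant_id", "modality", "melody_id"))
  list(kept = kept, excluded = tibble::as_tibble(excluded))
}

#' Per-note imitation errors
#'
#' Converts produced frequencies to cents on the task scale and pairs
#' them positionally with target notes. Call on *filtered* trials
#' (see [filter_trials()]): positional alignment is valid only when the
#' produced note count matches the target count.
#'
#' @param kept filtered trial rows.
#' @param profiles profile table carrying `root_hz` per
#'   participant/modality (the cents reference: the lowest scale degree
#'   of the stimulus set).
#' @return tibble of note errors: ids, `position`, `target_cents`,
#'   `produced_cents`, `error_cents` (produced - target) and
#'   `pitch_class` (target chromatic degree, 0-12).
#' @export
note_errors <- function(kept, profiles) {
  roots <- dplyr::distinct(profiles[, c("participant_id", "modality", "root_hz")])
  x <- dplyr::inner_join(kept, roots, by = c("participant_id", "modality"))
  x$produced_cents <- hz_to_cents(x$produced_hz, x$root_hz)
  x$error_cents <- x$produced_cents - x$target_cents
  x$pitch_class <- as.integer(round(x$target_cents / 100))
  tibble::as_tibble(x[, c(
    "participant_id", "modality", "melody_id", "position",
    "target_cents", "produced_cents", "error_cents", "pitch_class"
  )])
}

#' Per-interval imitation errors
#'
#' Intervals are differences between adjacent notes within a melody;
#' interval errors are produced interval minus target interval, which
#' makes them invariant to whole-melody transposition. The class used
#' for imprecision grouping is the target interval in semitones.
#'
#' @param errors note-error table from [note_errors()].
#' @return tibble of interval errors with `interval_position` (1 =
#'   between notes 1 and 2), `target_interval`, `produced_interval`,
#'   `error_cents`, `interval_class` (target interval, semitones).
#' @export
interval_errors <- function(errors) {
  x <- dplyr::arrange(errors, participant_id, modality, melody_id, position)
  x <- dplyr::group_by(x, participant_id, modality, melody_id)
  x <- dplyr::mutate(x,
    target_interval = target_cents - dplyr::lag(target_cents),
    produced_interval = produced_cents - dplyr::lag(produced_cents)
  )
  x <- dplyr::ungroup(x)
  x <- x[!is.na(x$target_interval), ]
  tibble::tibble(
    participant_id = x$participant_id, modality = x$modality,
    melody_id = x$melody_id, interval_position = x$position - 1L,
    target_interval = x$target_interval, produced_interval = x$produced_interval,
    error_cents = x$produced_interval - x$target_interval,
    interval_class = as.integer(round(x$target_interval / 100))
  )
}

#' Flag implausibly large note errors
#'
#' Notes whose absolute error exceeds the threshold (default 1000
#' cents) are flagged for verification as likely measurement or octave
#' errors. Each flagged note is annotated with its nearest-octave
#' corrected error. The default policy retains flagged notes; with
#' `octave_correct = TRUE` the correction replaces the error (and the
#' produced pitch) for flagged notes only.
#'
#' @param errors note-error table from [note_errors()].
#' @param threshold flag threshold in cents (default 1000).
#' @param octave_correct if `TRUE`, snap flagged notes to the nearest
#'   octave of the target before scoring.
#' @return list with `errors` (full table, corrected if requested;
#'   logical column `flagged` added) and `flagged` (the flagged subset
#'   with `octave_corrected_error`).
#' @export
flag_large_errors <- function(errors, threshold = 1000, octave_correct = FALSE) {
  flagged <- abs(errors$error_cents) > threshold
  corr <- errors$error_cents - 1200 * round(errors$error_cents / 1200)
  out <- errors
  out$flagged <- flagged
  flagged_tbl <- out[flagged, ]
  flagged_tbl$octave_corrected_error <- corr[flagged]
  if (octave_correct) {
    out$error_cents[flagged] <- corr[flagged]
    out$produced_cents[flagged] <- out$target_cents[flagged] + corr[flagged]
  }
  list(errors = out, flagged = tibble::as_tibble(flagged_tbl))
}

#' Inaccuracy: mean signed error
#'
#' The systematic component of imitation error — a consistent tendency
#' to err flat (negative) or sharp (positive).
#'
#' @param errors numeric vector of signed errors in cents.
#' @return mean signed error, cents.
#' @export
inaccuracy <- function(errors) {
  if (length(errors) == 0 || all(is.na(errors))) stop("no errors to average")
  mean(errors, na.rm = TRUE)
}

#' Imprecision: mean within-class SD of errors
#'
#' The variability of repeated attempts at the same pitch (or the same
#' interval): the sample standard deviation (denominator n - 1) of
#' errors within each class, averaged unweighted across classes.
#' Classes with fewer than two observations carry no variability
#' information and are dropped.
#'
#' @param errors numeric vector of signed errors in cents.
#' @param class class label per error (target pitch class for notes,
#'   target interval for intervals).
#' @return mean within-class SD, cents.
#' @export
imprecision <- function(errors, class) {
  stopifnot(length(errors) == length(class))
  keep <- !is.na(errors) & !is.na(class)
  errors <- errors[keep]
  class <- class[keep]
  n_by <- table(class)
  usable <- names(n_by)[n_by >= 2]
  if (length(usable) == 0) stop("no pitch class has >= 2 observations")
  sds <- tapply(errors[class %in% usable], as.character(class[class %in% usable]), stats::sd)
  mean(sds)
}

#' Per-participant accuracy and precision scores
#'
#' Computes, for each participant and modality, note- and
#' interval-level inaccuracy and imprecision over the kept trials,
#' together with trial bookkeeping and the perceptual covariate.
#'
#' @param filtered result of [filter_trials()] (list with `kept` and
#'   `excluded`), or a kept-trials table (then `n_excluded` is 0).
#' @param profiles profile table (needs `root_hz`; `mbea_percent` is
#'   carried through when present).
#' @param large_error_threshold cents threshold passed to
#'   [flag_large_errors()].
#' @param octave_correct whether to snap flagged notes to the nearest
#'   target octave before scoring (default `FALSE`: flagged notes are
#'   retained as-is).
#' @return a `score_table` tibble, one row per participant x modality:
#'   `note_inaccuracy`, `interval_inaccuracy`, `note_imprecision`,
#'   `interval_imprecision` (cents), `mbea_percent`, `n_trials_used`,
#'   `n_excluded`, `n_flagged`. Participant/modality cells with no
#'   usable trials appear with `NA` scores.
#' @export
score_participants <- function(filtered, profiles, large_error_threshold = 1000,
                               octave_correct = FALSE) {
  if (is.data.frame(filtered)) filtered <- list(kept = filtered, excluded = NULL)
  kept <- filtered$kept
  errs <- note_errors(kept, profiles)
  fl <- flag_large_errors(errs, threshold = large_error_threshold, octave_correct = octave_correct)
  errs <- fl$errors
  ints <- interval_errors(errs)

  note_dt <- data.table::as.data.table(errs)
  note_scores <- note_dt[, .(
    note_inaccuracy = mean(error_cents),
    note_imprecision = mean_class_sd(error_cents, pitch_class),
    n_trials_used = data.table::uniqueN(melody_id),
    n_flagged = sum(flagged)
  ), by = .(participant_id, modality)]
  int_dt <- data.table::as.data.table(ints)
  int_scores <- int_dt[, .(
    interval_inaccuracy = mean(error_cents),
    interval_imprecision = mean_class_sd(error_cents, interval_class)
  ), by = .(participant_id, modality)]

  scores <- dplyr::full_join(
    tibble::as_tibble(note_scores), tibble::as_tibble(int_scores),
    by = c("participant_id", "modality")
  )

  # every participant x modality present in profiles gets a row
  base <- dplyr::distinct(profiles[, c("participant_id", "modality")])
  scores <- dplyr::left_join(base, scores, by = c("participant_id", "modality"))
  scores$n_trials_used[is.na(scores$n_trials_used)] <- 0L

  if (!is.null(filtered$excluded) && nrow(filtered$excluded) > 0) {
    ex <- dplyr::count(filtered$excluded, participant_id, modality, name = "n_excluded")
    scores <- dplyr::left_join(scores, ex, by = c("participant_id", "modality"))
    scores$n_excluded[is.na(scores$n_excluded)] <- 0L
  } else {
    scores$n_excluded <- 0L
  }
  if ("mbea_percent" %in% names(profiles)) {
    mb <- dplyr::distinct(profiles[, c("participant_id", "mbea_percent")])
    scores <- dplyr::left_join(scores, mb, by = "participant_id")
  }
  out <- tibble::as_tibble(scores[, c(
    "participant_id", "modality", "note_inaccuracy", "interval_inaccuracy",
    "note_imprecision", "interval_imprecision",
    intersect("mbea_percent", names(scores)), "n_trials_used", "n_excluded", "n_flagged"
  )])
  class(out) <- c("score_table", class(out))
  out
}

# Imprecision kernel used in grouped scoring: mean over classes (>= 2
# obs) of the within-class sample SD; NA when no class qualifies.
mean_class_sd <- function(errors, class) {
  n_by <- table(class)
  usable <- names(n_by)[n_by >= 2]
  if (length(usable) == 0) {
    return(NA_real_)
  }
  keep <- as.character(class) %in% usable
  mean(tapply(errors[keep], as.character(class[keep]), stats::sd))
}

utils::globalVariables(c(
  ".", "participant_id", "modality", "melody_id", "position", "target_cents",
  "produced_cents", "error_cents", "pitch_class", "interval_class",
  "range_low_cents", "range_high_cents", "flagged", "out_of_range", "n_produced"
))
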