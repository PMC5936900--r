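#' Estimate fundamental frequency by autocorrelation
#'
#' F0 is extracted from the central 250 ms of the analysis window (the
#' steady portion of a note, avoiding onset and offset transients). The
#' method: remove the mean, compute the autocorrelation via FFT,
#' normalize by the lag-dependent overlap (unbiased estimate, which
#' removes the linear taper that would otherwise bias the peak
#' location), find autocorrelation peaks in the candidate lag range, and
#' take the shortest lag whose peak is within 5% of the global maximum
#' (guards against period-multiple errors). The peak lag is refined by
#' parabolic interpolation.
#'
#' Segments whose normalized peak autocorrelation falls below
#' `conf_threshold`, or whose energy is negligible, are flagged
#' unvoiced: the return value is `NA` with the confidence attached.
#'
#' @param w a `waveform`.
#' @param window `c(start_s, end_s)` of the note within `w`, in seconds;
#'   default the whole waveform.
#' @param centre_ms length of the central analysis segment (default 250).
#' @param fmin,fmax candidate F0 range in Hz (defaults 50 and 3000).
#' @param conf_threshold minimum normalized autocorrelation at the peak
#'   for the segment to count as voiced (default 0.5).
#' @return F0 in Hz, or `NA_real_` if unvoiced; the normalized peak
#'   autocorrelation is attached as attribute `"confidence"`.
#' @export
#' @examples
#' w <- synthesize_melody(0, pitch_range(440), synth_config())
#' estimate_f0(w)
estimate_f0 <- function(w, window = NULL, centre_ms = 250, fmin = 50, fmax = 3000,
                        conf_threshold = 0.5) {
  stopifnot(inherits(w, "waveform"))
  sr <- w$sample_rate
  x <- w$samples
  if (!is.null(window)) {
    i0 <- max(1L, floor(window[1] * sr) + 1L)
    i1 <- min(length(x), ceiling(window[2] * sr))
    if (i1 <= i0) stop("empty analysis window")
    x <- x[i0:i1]
  }
  n_take <- min(length(x), round(centre_ms / 1000 * sr))
  off <- (length(x) - n_take) %/% 2
  x <- x[off + seq_len(n_take)]
  x <- x - mean(x)
  n <- length(x)
  unvoiced <- function(conf) structure(NA_real_, confidence = conf)
  if (sqrt(mean(x^2)) < 1e-8) {
    return(unvoiced(0))
  }

  # FFT autocorrelation, unbiased normalization
  n2 <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, numeric(n2 - n)))
  ac <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[seq_len(n)] / n2
  ac_u <- ac / (n - (seq_len(n) - 1))
  r <- ac_u / ac_u[1]

  lag_min <- max(2L, floor(sr / fmax))
  lag_max <- min(n - 2L, ceiling(sr / fmin))
  if (lag_max <= lag_min) stop("analysis window too short for fmin")
  lags <- lag_min:lag_max
  rv <- r[lags + 1L]
  # local maxima within the candidate range
  is_peak <- rv > c(-Inf, rv[-length(rv)]) & rv >= c(rv[-1], -Inf)
  if (!any(is_peak)) {
    return(unvoiced(max(rv)))
  }
  peak_lags <- lags[is_peak]
  peak_vals <- rv[is_peak]
  best <- max(peak_vals)
  if (best < conf_threshold) {
    return(unvoiced(best))
  }
  lag0 <- peak_lags[which(peak_vals >= 0.95 * best)[1]]

  # parabolic refinement on the unbiased autocorrelation
  y1 <- ac_u[lag0]
  y2 <- ac_u[lag0 + 1L]
  y3 <- ac_u[lag0 + 2L]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  f0 <- sr / (lag0 + delta)
  structure(f0, confidence = r[lag0 + 1L])
}

#' Extract per-note F0 from a melody recording
#'
#' Applies [estimate_f0()] to each note window of an isochronous melody
#' laid out by the synthesis timing (or any user-supplied window table).
#'
#' @param w a `waveform` containing the whole melody.
#' @param windows a data frame with columns `position`, `start_s`,
#'   `end_s`; or `NULL` to derive windows for `n_notes` isochronous
#'   notes from `cfg`.
#' @param n_notes number of notes, used when `windows` is `NULL`.
#' @param cfg a [synth_config()] supplying note/gap durations.
#' @inheritParams estimate_f0
#' @return tibble with `position`, `f0_hz`, `confidence`.
#' @export
extract_f0_notes <- function(w, windows = NULL, n_notes = 5, cfg = synth_config(),
                             conf_threshold = 0.5) {
  if (is.null(windows)) {
    step <- (cfg$note_duration_ms + cfg$gap_duration_ms) / 1000
    windows <- tibble::tibble(
      position = seq_len(n_notes),
      start_s = (position - 1) * step,
      end_s = (position - 1) * step + cfg$note_duration_ms / 1000
    )
  }
  res <- lapply(seq_len(nrow(windows)), function(i) {
    f0 <- estimate_f0(w,
      window = c(windows$start_s[i], windows$end_s[i]),
      conf_threshold = conf_threshold
    )
    tibble::tibble(
      position = windows$position[i],
      f0_hz = as.numeric(f0),
      confidence = attr(f0, "confidence")
    )
  })
  dplyr::bind_rows(res)
}
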