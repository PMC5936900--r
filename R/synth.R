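#' Configuration for whistle-timbre stimulus synthesis
#'
#' Stimuli are isochronous sine-tone notes separated by short silences,
#' each note shaped by an onset amplitude envelope. The envelope is
#' parametric: a raised-cosine attack, a sustained body at the peak
#' level, and a short raised-cosine release.
#'
#' @param sample_rate samples per second (default 44100).
#' @param bit_depth PCM bit depth used when writing WAV (default 16).
#' @param note_duration_ms duration of each note, ms (default 750).
#' @param gap_duration_ms silence between notes, ms (default 50).
#' @param attack_ms raised-cosine attack time, ms (default 40).
#' @param release_ms raised-cosine release time, ms (default 20).
#' @param level linear peak amplitude, in (0, 1] (default 0.9); equal
#'   across notes so all stimuli share one peak sound-pressure level.
#' @return a `synth_config` list.
#' @export
synth_config <- function(sample_rate = 44100, bit_depth = 16, note_duration_ms = 750,
                         gap_duration_ms = 50, attack_ms = 40, release_ms = 20,
                         level = 0.9) {
  stopifnot(
    sample_rate > 0, note_duration_ms > 0, gap_duration_ms >= 0,
    attack_ms >= 0, release_ms >= 0, level > 0, level <= 1,
    attack_ms + release_ms <= note_duration_ms
  )
  structure(
    list(
      sample_rate = sample_rate, bit_depth = as.integer(bit_depth),
      note_duration_ms = note_duration_ms, gap_duration_ms = gap_duration_ms,
      attack_ms = attack_ms, release_ms = release_ms, level = level
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %g Hz / %d bit; note %g ms + gap %g ms; attack %g ms; level %.2f\n",
    x$sample_rate, x$bit_depth, x$note_duration_ms, x$gap_duration_ms, x$attack_ms, x$level
  ))
  invisible(x)
}

# Onset/offset amplitude envelope for one note, as a multiplicative gain.
note_envelope <- function(n_samples, cfg) {
  env <- rep(1, n_samples)
  na <- round(cfg$attack_ms / 1000 * cfg$sample_rate)
  nr <- round(cfg$release_ms / 1000 * cfg$sample_rate)
  if (na > 0) env[seq_len(na)] <- 0.5 - 0.5 * cos(pi * seq_len(na) / na)
  if (nr > 0) {
    idx <- n_samples - nr + seq_len(nr)
    env[idx] <- pmin(env[idx], 0.5 + 0.5 * cos(pi * seq_len(nr) / nr))
  }
  env
}

#' Construct a waveform object
#'
#' A waveform is a numeric sample vector in `[-1, 1]` plus its sample
#' rate. Use this to wrap externally recorded audio for
#' [estimate_f0()] or [write_wav()].
#'
#' @param samples numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate samples per second.
#' @return a `waveform` object.
#' @export
waveform <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  structure(list(samples = samples, sample_rate = sample_rate), class = "waveform")
}

new_waveform <- waveform

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform> %d samples @ %g Hz (%.3f s), peak %.3f\n",
    length(x$samples), x$sample_rate, length(x$samples) / x$sample_rate,
    max(abs(x$samples))
  ))
  invisible(x)
}

#' Synthesize a melody as a whistle-timbre waveform
#'
#' Each scale degree becomes a sine tone at its equal-temperament
#' frequency, shaped by the onset envelope, at a common peak level;
#' notes are separated by exactly-zero gaps.
#'
#' @param degrees integer scale degrees (a melody, e.g. from
#'   [compose_melody()]).
#' @param range a [pitch_range()] giving the root frequency.
#' @param cfg a [synth_config()].
#' @return a `waveform` (samples in `[-1, 1]` plus sample rate).
#' @export
#' @examples
#' w <- synthesize_melody(c(0, 2, 4), pitch_range(880), synth_config())
synthesize_melody <- function(degrees, range, cfg = synth_config()) {
  stopifnot(length(degrees) >= 1, inherits(cfg, "synth_config"))
  freqs <- degree_to_hz(degrees, range)
  if (any(freqs >= cfg$sample_rate / 2)) {
    stop("note frequency at or above Nyquist (", cfg$sample_rate / 2, " Hz)")
  }
  n_note <- round(cfg$note_duration_ms / 1000 * cfg$sample_rate)
  n_gap <- round(cfg$gap_duration_ms / 1000 * cfg$sample_rate)
  env <- note_envelope(n_note, cfg)
  t <- seq_len(n_note) / cfg$sample_rate
  segs <- vector("list", 2 * length(freqs) - 1)
  for (i in seq_along(freqs)) {
    segs[[2 * i - 1]] <- cfg$level * env * sin(2 * pi * freqs[i] * t)
    if (i < length(freqs)) segs[[2 * i]] <- numeric(n_gap)
  }
  new_waveform(unlist(segs), cfg$sample_rate)
}

#' Synthesize a melody set to WAV files
#'
#' One file per melody plus a manifest CSV recording ids, files, roots
#' and note timing (note windows in seconds, usable by [estimate_f0()]).
#'
#' @param melodies tidy melody tibble from [compose_set()].
#' @param range a [pitch_range()].
#' @param out_dir output directory (created if missing).
#' @param cfg a [synth_config()].
#' @return the manifest tibble, invisibly written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
synthesize_set <- function(melodies, range, out_dir, cfg = synth_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  step_s <- (cfg$note_duration_ms + cfg$gap_duration_ms) / 1000
  rows <- lapply(split(melodies, melodies$melody_id), function(m) {
    m <- m[order(m$position), ]
    w <- synthesize_melody(m$degree, range, cfg)
    file <- file.path(out_dir, paste0(m$melody_id[1], ".wav"))
    write_wav(w, file, cfg$bit_depth)
    tibble::tibble(
      melody_id = m$melody_id, position = m$position, degree = m$degree,
      file = basename(file), root_hz = degree_to_hz(0, range),
      start_s = (m$position - 1) * step_s,
      end_s = (m$position - 1) * step_s + cfg$note_duration_ms / 1000
    )
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
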