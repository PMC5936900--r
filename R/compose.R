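#' Configuration for random melody composition
#'
#' Melodies are short sequences of chromatic scale degrees composed by a
#' constrained random walk: the first note is drawn uniformly from the
#' chromatic scale, each subsequent interval uniformly from the integers
#' `-max_interval..max_interval`, and the whole melody is rejection-sampled
#' until every note lies within a single octave.
#'
#' @param n_melodies number of melodies in a set (default 45).
#' @param n_notes notes per melody (default 5).
#' @param max_interval largest permitted adjacent-note interval, in
#'   semitones (default 4).
#' @param octave_span permitted melody compass in semitones; all notes must
#'   lie in `[0, octave_span]` (default 12, one octave).
#' @param seed integer root seed for the composition stream.
#' @return a `composition_config` list.
#' @export
#' @examples
#' composition_config()
composition_config <- function(n_melodies = 45, n_notes = 5, max_interval = 4,
                               octave_span = 12, seed = 1) {
  stopifnot(n_melodies >= 1, n_notes >= 2)
  if (max_interval < 1) {
    stop("max_interval must be >= 1 (a zero interval cap cannot move off the first note)")
  }
  if (octave_span < max_interval) {
    stop("octave_span must be >= max_interval")
  }
  structure(
    list(
      n_melodies = as.integer(n_melodies), n_notes = as.integer(n_notes),
      max_interval = as.integer(max_interval), octave_span = as.integer(octave_span),
      seed = as.integer(seed)
    ),
    class = "composition_config"
  )
}

#' @export
print.composition_config <- function(x, ...) {
  cat(sprintf(
    "<composition_config> %d melodies x %d notes; |interval| <= %d st; span <= %d st; seed %d\n",
    x$n_melodies, x$n_notes, x$max_interval, x$octave_span, x$seed
  ))
  invisible(x)
}

#' Compose one melody under interval and octave constraints
#'
#' First note uniform on the chromatic degrees `0..octave_span - 1`;
#' each following interval uniform on `-max_interval..max_interval`
#' (zero, a repeated note, is permitted). The melody as a whole is
#' rejection-sampled until every note falls in `[0, octave_span]`, which
#' also bounds the compass by one octave at the defaults.
#'
#' @param config a [composition_config()].
#' @param seed seed for this melody's sub-stream; defaults to the config seed.
#' @param max_tries rejection-sampling cap; exceeded only under a
#'   misconfiguration, in which case an error is raised.
#' @return integer vector of scale degrees, length `config$n_notes`.
#' @export
#' @examples
#' compose_melody(composition_config(), seed = 7)
compose_melody <- function(config, seed = config$seed, max_tries = 100000L) {
  stopifnot(inherits(config, "composition_config"))
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      first <- sample.int(config$octave_span, 1L) - 1L # degrees 0..octave_span-1
      steps <- sample.int(2L * config$max_interval + 1L, config$n_notes - 1L,
        replace = TRUE
      ) - config$max_interval - 1L
      notes <- cumsum(c(first, steps))
      if (all(notes >= 0L & notes <= config$octave_span)) {
        return(as.integer(notes))
      }
    }
    stop("rejection sampling failed after ", max_tries, " attempts; check config")
  })
}

#' Compose a set of melodies
#'
#' Each melody uses its own sub-stream derived from the set seed and the
#' melody index, so the set is reproducible and order-independent.
#'
#' @inheritParams compose_melody
#' @return a tibble with columns `melody_id`, `position` (1-based note
#'   index) and `degree` (semitones above the scale root).
#' @export
#' @examples
#' head(compose_set(composition_config(n_melodies = 3)))
compose_set <- function(config) {
  stopifnot(inherits(config, "composition_config"))
  mel <- lapply(seq_len(config$n_melodies), function(i) {
    notes <- compose_melody(config, seed = derive_seed(config$seed, paste0("melody", i)))
    tibble::tibble(
      melody_id = sprintf("m%02d", i),
      position = seq_along(notes),
      degree = notes
    )
  })
  dplyr::bind_rows(mel)
}

#' A pitch range: equal-temperament scale anchored at a root frequency
#'
#' The task octave for one stimulus condition. Scale degree 0 sounds at
#' `root_hz`; degree 12 one octave above.
#'
#' @param root_hz frequency of scale degree 0, in Hz.
#' @param label condition label (e.g. `"whistled"`).
#' @return a `pitch_range` list.
#' @export
pitch_range <- function(root_hz, label = "") {
  stopifnot(is.numeric(root_hz), length(root_hz) == 1, root_hz > 0)
  structure(list(root_hz = as.numeric(root_hz), label = label), class = "pitch_range")
}

#' @export
print.pitch_range <- function(x, ...) {
  cat(sprintf("<pitch_range> %s: root %.1f Hz (octave to %.1f Hz)\n", x$label, x$root_hz, 2 * x$root_hz))
  invisible(x)
}

#' The stimulus ranges of the imitation task
#'
#' Male-sung melodies span A2-A3 (root 110 Hz), female-sung A3-A4
#' (root 220 Hz), and whistled-timbre stimuli A5-A6 (root 880 Hz).
#'
#' @return named list of [pitch_range()] objects.
#' @export
task_pitch_ranges <- function() {
  list(
    male_sung = pitch_range(110, "male-sung"),
    female_sung = pitch_range(220, "female-sung"),
    whistled = pitch_range(880, "whistled")
  )
}

#' Convert a scale degree to frequency
#'
#' Equal temperament: `root_hz * 2^(degree / 12)`.
#'
#' @param degree semitones above the range root (may be fractional).
#' @param range a [pitch_range()] or a bare root frequency in Hz.
#' @return frequency in Hz.
#' @export
#' @examples
#' degree_to_hz(12, pitch_range(110)) # 220 Hz, one octave up
degree_to_hz <- function(degree, range) {
  root <- if (inherits(range, "pitch_range")) range$root_hz else as.numeric(range)
  stopifnot(is.numeric(root), root > 0)
  root * 2^(degree / 12)
}

#' Write / read a melody set as CSV
#'
#' Plain tidy CSV with columns `melody_id`, `position`, `degree`.
#'
#' @param melodies tibble from [compose_set()].
#' @param path file path.
#' @return `write_melodies` returns `path` invisibly; `read_melodies`
#'   returns the melody tibble.
#' @export
write_melodies <- function(melodies, path) {
  stopifnot(all(c("melody_id", "position", "degree") %in% names(melodies)))
  readr::write_csv(melodies, path)
  invisible(path)
}

#' @rdname write_melodies
#' @export
read_melodies <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    melody_id = readr::col_character(),
    position = readr::col_integer(),
    degree = readr::col_integer()
  ))
}
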