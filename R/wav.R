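#' Write a waveform to a PCM WAV file
#'
#' Minimal RIFF/WAVE writer: mono, integer PCM, little-endian. Samples
#' must already lie in `[-1, 1]`; they are scaled by `2^(bits-1) - 1`
#' and rounded, so a write/read round trip is exact to half an LSB.
#'
#' @param w a `waveform` (see [synthesize_melody()]).
#' @param path output file path.
#' @param bit_depth 16 (default) or 8 bits per sample.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bit_depth = 16) {
  stopifnot(inherits(w, "waveform"), bit_depth %in% c(8L, 16L))
  if (any(abs(w$samples) > 1 + 1e-12)) stop("samples outside [-1, 1]")
  n <- length(w$samples)
  bytes_per <- bit_depth / 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  put_u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  put_u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  put_u32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  put_u32(16) # PCM fmt chunk size
  put_u16(1) # audio format 1 = integer PCM
  put_u16(1) # mono
  put_u32(w$sample_rate)
  put_u32(w$sample_rate * bytes_per) # byte rate
  put_u16(bytes_per) # block align
  put_u16(bit_depth)
  writeChar("data", con, eos = NULL)
  put_u32(data_size)
  if (bit_depth == 16) {
    writeBin(as.integer(round(w$samples * 32767)), con, size = 2, endian = "little")
  } else {
    # 8-bit WAV is unsigned, midpoint 128
    writeBin(as.raw(round(w$samples * 127) + 128), con)
  }
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Parses the RIFF chunk list (tolerating extra chunks such as LIST),
#' accepts mono integer PCM at 8 or 16 bits, and rescales samples to
#' `[-1, 1]`.
#'
#' @param path WAV file path.
#' @return a `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  get_u32 <- function() readBin(con, "integer", size = 4, endian = "little")
  get_u16 <- function() readBin(con, "integer", size = 2, endian = "little", signed = FALSE)
  if (!identical(readChar(con, 4), "RIFF")) stop("not a RIFF file")
  get_u32()
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file")
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- get_u32()
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = get_u16(), channels = get_u16(), sample_rate = get_u32(),
        byte_rate = get_u32(), block_align = get_u16(), bits = get_u16()
      )
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$format != 1) stop("unsupported WAV encoding (only integer PCM)")
      if (fmt$channels != 1) stop("only mono WAV files are supported")
      if (fmt$bits == 16) {
        raw16 <- readBin(con, "integer", n = size / 2, size = 2, endian = "little")
        samples <- raw16 / 32767
      } else if (fmt$bits == 8) {
        raw8 <- as.integer(readBin(con, "raw", n = size))
        samples <- (raw8 - 128) / 127
      } else {
        stop("unsupported bit depth: ", fmt$bits)
      }
      if (size %% 2 == 1) readBin(con, "raw", 1) # chunk padding
    } else {
      readBin(con, "raw", size + size %% 2) # skip unknown chunk
    }
    if (!is.null(samples)) break
  }
  if (is.null(fmt) || is.null(samples)) stop("malformed WAV: missing fmt or data chunk")
  new_waveform(samples, fmt$sample_rate)
}
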