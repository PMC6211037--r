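## AudioSignal container and PCM WAV I/O.
##
## Samples are stored as a numeric vector (mono) or an n x 2 matrix (stereo)
## on the [-1, 1] scale; `rate` is the sampling rate in Hz.  WAV files are
## plain RIFF/WAVE PCM; 16- and 24-bit integer encodings are supported and
## both are decoded with the same convention (divide by 2^(bits-1)) so that
## bit depth never changes the amplitude scale.

#' Construct an audio signal
#'
#' @param samples Numeric vector (mono) or two-column matrix (stereo) of
#'   amplitudes, nominally in `[-1, 1]`.
#' @param rate Sampling rate in Hz.
#' @param bit_depth Nominal bit depth used when the signal is written to disk.
#' @return An object of class `audio_signal`.
#' @export
audio_signal <- function(samples, rate, bit_depth = 16L) {
  if (is.matrix(samples) && ncol(samples) == 1L) samples <- samples[, 1L]
  if (is.matrix(samples) && ncol(samples) > 2L) {
    stop("only mono or stereo signals are supported", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a positive sampling rate in Hz", call. = FALSE)
  }
  structure(
    list(samples = samples, rate = as.numeric(rate),
         bit_depth = as.integer(bit_depth)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d channel(s), %d samples @ %g Hz (%.3f s)\n",
              n_channels(x), n_samples(x), x$rate, duration(x)))
  invisible(x)
}

#' Number of channels of an audio signal
#' @param signal An `audio_signal`.
#' @return 1 or 2.
#' @export
n_channels <- function(signal) if (is.matrix(signal$samples)) ncol(signal$samples) else 1L

#' Number of sample frames of an audio signal
#' @param signal An `audio_signal`.
#' @return Integer frame count.
#' @export
n_samples <- function(signal) NROW(signal$samples)

#' Duration of an audio signal in seconds
#' @param signal An `audio_signal`.
#' @return Duration in seconds.
#' @export
duration <- function(signal) n_samples(signal) / signal$rate

#' Read a PCM WAV file
#'
#' Reads RIFF/WAVE PCM audio (16- or 24-bit integer, mono or stereo).
#' Amplitudes are scaled to `[-1, 1]` by `2^(bits-1)` regardless of bit
#' depth; stereo is retained (channel selection is done later with
#' [to_mono()]).
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # chunk size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        channels     = sum(as.integer(body[3:4]) * c(1, 256)),
        rate         = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size) {
        stop("truncated WAV data chunk in ", path, call. = FALSE)
      }
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip with pad byte
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("missing fmt/data chunk in WAV file: ", path, call. = FALSE)
  }
  if (fmt$audio_format != 1L) {
    stop("only integer PCM WAV is supported (format tag ",
         fmt$audio_format, ")", call. = FALSE)
  }
  bytes <- fmt$bits / 8L
  if (!fmt$bits %in% c(16L, 24L)) {
    stop("unsupported bit depth: ", fmt$bits, call. = FALSE)
  }
  n <- length(data_raw) %/% (bytes * fmt$channels)
  if (fmt$bits == 16L) {
    ints <- readBin(data_raw, "integer", n * fmt$channels, size = 2L,
                    signed = TRUE, endian = "little")
  } else {
    b <- as.integer(data_raw[seq_len(n * fmt$channels * 3L)])
    b1 <- b[seq(1L, length(b), by = 3L)]
    b2 <- b[seq(2L, length(b), by = 3L)]
    b3 <- b[seq(3L, length(b), by = 3L)]
    ints <- b1 + b2 * 256 + b3 * 65536
    ints <- ifelse(ints >= 8388608, ints - 16777216, ints)
  }
  x <- ints / 2^(fmt$bits - 1L)
  if (fmt$channels == 2L) {
    x <- cbind(left = x[seq(1L, length(x), 2L)], right = x[seq(2L, length(x), 2L)])
  }
  audio_signal(x, fmt$rate, bit_depth = fmt$bits)
}

#' Write a PCM WAV file
#'
#' Writes 16-bit (default) or 24-bit integer PCM.  Samples are clipped to
#' `[-1, 1]` and quantized symmetrically with the same `2^(bits-1)`
#' convention used by [read_wav()].
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @param bit_depth 16 or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bit_depth = 16L) {
  stopifnot(inherits(signal, "audio_signal"), bit_depth %in% c(16L, 24L))
  x <- signal$samples
  if (is.matrix(x)) x <- as.vector(t(x))  # interleave
  x <- pmin(pmax(x, -1), 1)
  full <- 2^(bit_depth - 1L)
  ints <- as.integer(pmin(pmax(round(x * full), -full), full - 1))
  ch <- n_channels(signal)
  bytes <- bit_depth / 8L
  data_size <- length(ints) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")                       # PCM
  writeBin(as.integer(ch), con, size = 2L, endian = "little")
  writeBin(as.integer(signal$rate), con, size = 4L, endian = "little")
  writeBin(as.integer(signal$rate * ch * bytes), con, size = 4L, endian = "little")
  writeBin(as.integer(ch * bytes), con, size = 2L, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bit_depth == 16L) {
    writeBin(ints, con, size = 2L, endian = "little")
  } else {
    u <- ifelse(ints < 0L, ints + 16777216, ints)
    raw3 <- as.raw(rbind(u %% 256, (u %/% 256) %% 256, (u %/% 65536) %% 256))
    writeBin(raw3, con)
  }
  invisible(path)
}
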