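## Preprocessing chain applied to every duet recording before feature
## extraction: split to mono, downsample to 44.1 kHz when necessary,
## high-pass at 80 Hz to strip low-frequency noise, normalize the loudest
## peak to full scale.  Filters are 4th-order Butterworth run forward and
## backward (zero phase) so that onset timing used by the temporal features
## is not shifted.

#' Reduce a signal to a single channel
#'
#' @param signal An [audio_signal()].
#' @param channel One of `"left"` (default), `"right"`, `"mix"`.  `"mix"`
#'   averages the two channels.  A mono input is returned unchanged.
#' @return A mono [audio_signal()].
#' @export
to_mono <- function(signal, channel = c("left", "right", "mix")) {
  channel <- match.arg(channel)
  if (n_channels(signal) == 1L) return(signal)
  x <- switch(channel,
    left  = signal$samples[, 1L],
    right = signal$samples[, 2L],
    mix   = rowMeans(signal$samples)
  )
  audio_signal(x, signal$rate, signal$bit_depth)
}

#' Resample an audio signal
#'
#' Polyphase FIR resampling (via [signal::resample()]) with an anti-aliasing
#' filter; in the analysis pipeline it is used for downsampling only
#' (e.g. 96 kHz or 48 kHz recordings to 44.1 kHz).
#'
#' @param signal An [audio_signal()].
#' @param target_rate Target sampling rate in Hz.
#' @return An [audio_signal()] at `target_rate`.
#' @export
resample_audio <- function(signal, target_rate) {
  stopifnot(inherits(signal, "audio_signal"), target_rate > 0)
  if (target_rate == signal$rate) return(signal)
  frac <- .rat_approx(target_rate / signal$rate)
  res1 <- function(x) {
    y <- signal::resample(x, frac$p, frac$q)
    n_out <- round(length(x) * target_rate / signal$rate)
    length(y) <- n_out  # pad/trim to preserve duration within one sample
    y[is.na(y)] <- 0
    y
  }
  x <- signal$samples
  y <- if (is.matrix(x)) apply(x, 2L, res1) else res1(x)
  audio_signal(y, target_rate, signal$bit_depth)
}

## Small continued-fraction rational approximation of a rate ratio.
.rat_approx <- function(r, max_den = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) { best <- c(p, q); err <- e }
    if (err < 1e-12) break
  }
  list(p = best[1L], q = best[2L])
}

#' High-pass / low-pass filter chain
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth high-pass
#' at `high_pass` Hz and, optionally, a low-pass at `low_pass` Hz.  The
#' effective response is 8th order with squared magnitude, giving roughly
#' 48 dB attenuation one octave below an 80 Hz high-pass cutoff.
#'
#' @param signal A mono [audio_signal()].
#' @param high_pass High-pass cutoff in Hz, or `NULL` to skip.
#' @param low_pass Low-pass cutoff in Hz, or `NULL` to skip.
#' @param order Butterworth order per pass.
#' @return The filtered [audio_signal()].
#' @export
bandpass_chain <- function(signal, high_pass = 80, low_pass = NULL, order = 4L) {
  stopifnot(inherits(signal, "audio_signal"))
  if (n_channels(signal) != 1L) stop("filter a mono signal", call. = FALSE)
  nyq <- signal$rate / 2
  x <- signal$samples
  for (spec in list(list(f = high_pass, type = "high"),
                    list(f = low_pass, type = "low"))) {
    if (is.null(spec$f)) next
    if (spec$f >= nyq) {
      stop(sprintf("cutoff %g Hz is at or above Nyquist (%g Hz)", spec$f, nyq),
           call. = FALSE)
    }
    bt <- signal::butter(order, spec$f / nyq, type = spec$type)
    x <- signal::filtfilt(bt, x)
  }
  audio_signal(x, signal$rate, signal$bit_depth)
}

#' Normalize the loudest peak to full scale
#'
#' Scales the signal so that `max(abs(samples)) == 1`, preserving all
#' relative amplitudes, so the loudest peak is identical across files.
#'
#' @param signal An [audio_signal()].
#' @return The normalized [audio_signal()].
#' @export
normalize_peak <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  peak <- max(abs(signal$samples))
  if (peak == 0) stop("cannot normalize an all-zero (silent) signal", call. = FALSE)
  audio_signal(signal$samples / peak, signal$rate, signal$bit_depth)
}

#' Standard preprocessing chain for a duet recording
#'
#' Mono split, downsample to `target_rate` when the source rate is higher,
#' high-pass at 80 Hz, peak normalization.
#'
#' @param signal An [audio_signal()].
#' @param channel Channel passed to [to_mono()].
#' @param target_rate Analysis rate in Hz (default 44100).
#' @param high_pass High-pass cutoff in Hz.
#' @param normalize Whether to apply [normalize_peak()].
#' @return A conditioned mono [audio_signal()].
#' @export
preprocess_audio <- function(signal, channel = "left", target_rate = 44100,
                             high_pass = 80, normalize = TRUE) {
  s <- to_mono(signal, channel)
  if (s$rate > target_rate) s <- resample_audio(s, target_rate)
  if (!is.null(high_pass)) s <- bandpass_chain(s, high_pass = high_pass)
  if (normalize) s <- normalize_peak(s)
  s
}
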