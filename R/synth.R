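## Synthetic duet generator.
##
## Field recordings of titi duets are rarely archived, so every downstream
## stage is exercised against synthetic duets whose acoustic and temporal
## statistics are controlled by species profiles.  The sound model is
## deliberately schematic: bellows are harmonic stacks with slow FM, pants
## and terminal elements are band-limited noise bursts, pumps are short
## high-rate pulse series, arches and whinnies are tonal FM sweeps, hoots
## and moans are low narrowband tones.  `carrier` is the spectral centre of
## a syllable, `bandwidth` the FM depth (tonal part) and noise band width,
## `noisiness` the noise fraction of total energy.

#' Describe a syllable class
#'
#' @param name Syllable class name (e.g. `"pant"`, `"bellow"`, `"pump"`).
#' @param carrier Centre frequency in Hz.
#' @param duration Duration in seconds.
#' @param bandwidth FM depth / noise band width in Hz.
#' @param contour Frequency trajectory: `"flat"`, `"rise"`, `"fall"`, `"arch"`.
#' @param harmonic_count Number of harmonics of the tonal component.
#' @param noisiness Fraction of energy carried by band-limited noise, in
#'   `[0, 1]`.
#' @param amplitude Relative linear peak gain (> 0).
#' @return A `syllable_template` object.
#' @export
syllable_template <- function(name, carrier, duration, bandwidth = 0,
                              contour = c("flat", "rise", "fall", "arch"),
                              harmonic_count = 1L, noisiness = 0,
                              amplitude = 1) {
  contour <- match.arg(contour)
  stopifnot(is.character(name), length(name) == 1L)
  if (duration <= 0) stop("syllable duration must be > 0", call. = FALSE)
  if (carrier - bandwidth / 2 <= 0) {
    stop("carrier - bandwidth/2 must be > 0", call. = FALSE)
  }
  if (noisiness < 0 || noisiness > 1) {
    stop("noisiness must lie in [0, 1]", call. = FALSE)
  }
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  structure(
    list(name = name, carrier = carrier, bandwidth = bandwidth,
         duration = duration, contour = contour,
         harmonic_count = as.integer(harmonic_count),
         noisiness = noisiness, amplitude = amplitude),
    class = "syllable_template"
  )
}

## Frequency deviation trajectory over normalized time u in [0, 1].
.contour_dev <- function(contour, bw, u) {
  if (bw == 0) return(rep(0, length(u)))
  switch(contour,
    flat = rep(0, length(u)),
    rise = bw * (u - 0.5),
    fall = bw * (0.5 - u),
    arch = bw / 2 * (2 * sin(pi * u) - 1)
  )
}

#' Render one syllable to audio
#'
#' Produces a waveform of the template's stated duration (within one
#' sample).  The tonal part is a harmonic stack (power rolling off as
#' 1/h^3) following the contour trajectory; the noise part is Gaussian
#' noise band-limited to `carrier +/- bandwidth/2`; both are mixed by
#' `noisiness` (energy fraction), shaped by a raised-cosine onset/offset
#' ramp, and peak-scaled to `amplitude`.
#'
#' @param template A [syllable_template()].
#' @param rate_hz Sampling rate in Hz; all carrier content (including the
#'   highest harmonic and the upper noise edge) must lie below Nyquist.
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @return An [audio_signal()].
#' @export
render_syllable <- function(template, rate_hz, seed = 1L) {
  stopifnot(inherits(template, "syllable_template"))
  top_tonal <- template$carrier * template$harmonic_count + template$bandwidth / 2
  top_noise <- if (template$noisiness > 0) template$carrier + template$bandwidth / 2 else 0
  top <- max(if (template$noisiness < 1) top_tonal else 0, top_noise)
  if (top >= rate_hz / 2) {
    stop(sprintf(
      "aliasing: spectral content up to %.0f Hz exceeds Nyquist (%.0f Hz)",
      top, rate_hz / 2), call. = FALSE)
  }
  n <- max(2L, round(template$duration * rate_hz))
  u <- (seq_len(n) - 1) / (n - 1)
  with_rng_seed(seed, {
    x <- numeric(n)
    if (template$noisiness < 1) {
      f_inst <- template$carrier + .contour_dev(template$contour, template$bandwidth, u)
      phase <- 2 * pi * cumsum(f_inst) / rate_hz
      tonal <- numeric(n)
      for (h in seq_len(template$harmonic_count)) {
        tonal <- tonal + h^(-1.5) * sin(h * phase + runif(1, 0, 2 * pi))
      }
      tonal <- tonal / sqrt(mean(tonal^2))
      x <- x + sqrt(1 - template$noisiness) * tonal
    }
    if (template$noisiness > 0) {
      bw <- max(template$bandwidth, 50)  # a zero-width noise band is degenerate
      noise <- .bandlimited_noise(n, rate_hz, template$carrier - bw / 2,
                                  template$carrier + bw / 2)
      x <- x + sqrt(template$noisiness) * noise
    }
    x <- x * .cos_ramp(n, ramp = min(0.1 * template$duration, 0.01) * rate_hz)
    audio_signal(x / max(abs(x)) * template$amplitude, rate_hz)
  })
}

## Gaussian noise confined to [f_lo, f_hi] via an FFT brick-wall mask,
## unit RMS.  Uses the caller's RNG stream.
.bandlimited_noise <- function(n, rate_hz, f_lo, f_hi) {
  w <- rnorm(n)
  spec <- fft(w)
  freqs <- (seq_len(n) - 1) * rate_hz / n
  freqs <- pmin(freqs, rate_hz - freqs)  # fold to [0, Nyquist]
  mask <- freqs >= max(f_lo, 0) & freqs <= f_hi
  spec[!mask] <- 0
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

.cos_ramp <- function(n, ramp) {
  ramp <- max(2L, min(round(ramp), floor(n / 2)))
  env <- rep(1, n)
  up <- 0.5 * (1 - cos(pi * (seq_len(ramp) - 1) / (ramp - 1)))
  env[seq_len(ramp)] <- up
  env[n + 1 - seq_len(ramp)] <- up
  env
}

#' Specify a phrase (a run of repeated syllables by one voice)
#'
#' @param syllable A [syllable_template()].
#' @param count_range Integer interval `c(min, max)` for the number of
#'   syllables; `min >= 1`.
#' @param rate Call rate in calls/s (onset-to-onset), > 0.
#' @param voice `"m"` or `"f"`.
#' @param phrase Phrase label; defaults to the syllable name.
#' @param rate_trend Rate multiplier trajectory across the phrase: the
#'   instantaneous rate ramps linearly from `rate * rate_trend` to
#'   `rate * (2 - rate_trend)`.  Values < 1 produce a crescendo-like
#'   slow-then-fast pattern (first half slower than second half); 1 is a
#'   uniform rate.  When `rate_trend != 1` syllables are tagged with
#'   `"cresc"`/`"decresc"` sub-phases (first half / second half).
#' @param jitter_cv Coefficient of variation of Gaussian per-interval
#'   timing jitter (truncated at 3 CV; onsets stay ordered).
#' @param duration Optional phrase duration in seconds; if supplied it must
#'   agree with `(count - 1) / rate` within 20%, otherwise an error is
#'   raised (rate/duration inconsistency guard).
#' @return A `phrase_spec` object.
#' @export
phrase_spec <- function(syllable, count_range, rate, voice = c("m", "f"),
                        phrase = syllable$name, rate_trend = 1,
                        jitter_cv = 0.05, duration = NULL) {
  voice <- match.arg(voice)
  stopifnot(inherits(syllable, "syllable_template"))
  count_range <- as.integer(round(count_range))
  if (length(count_range) == 1L) count_range <- rep(count_range, 2L)
  if (count_range[1L] < 1L || count_range[2L] < count_range[1L]) {
    stop("count_range must be an increasing integer interval with min >= 1",
         call. = FALSE)
  }
  if (rate <= 0) stop("phrase rate must be > 0", call. = FALSE)
  if (!is.null(duration)) {
    implied <- (mean(count_range) - 1) / rate
    if (implied > 0 && abs(duration - implied) > 0.2 * implied) {
      stop(sprintf(
        "phrase duration %.2f s inconsistent with rate %.2f calls/s and count %g",
        duration, rate, mean(count_range)), call. = FALSE)
    }
  }
  structure(
    list(syllable = syllable, count_range = count_range, rate = rate,
         voice = voice, phrase = phrase, rate_trend = rate_trend,
         jitter_cv = jitter_cv),
    class = "phrase_spec"
  )
}

#' Build one phrase: audio plus syllable annotations
#'
#' Onsets are spaced at the phrase rate (with the `rate_trend` ramp and
#' truncated Gaussian jitter); each syllable is rendered from the template
#' and summed into a common buffer.  With zero jitter and a flat trend the
#' onsets are exactly `(i - 1) / rate`.
#'
#' @param spec A [phrase_spec()].
#' @param rate_hz Sampling rate in Hz.
#' @param seed Integer seed.
#' @return A list with `signal` (an [audio_signal()]) and `events` (an
#'   [annotation_track()] with one row per syllable).
#' @export
build_phrase <- function(spec, rate_hz = 44100, seed = 1L) {
  stopifnot(inherits(spec, "phrase_spec"))
  with_rng_seed(seed, {
    count <- if (spec$count_range[1L] == spec$count_range[2L]) {
      spec$count_range[1L]
    } else {
      sample(spec$count_range[1L]:spec$count_range[2L], 1L)
    }
    onsets <- .phrase_onsets(count, spec$rate, spec$rate_trend, spec$jitter_cv)
    syl_seeds <- sample.int(.Machine$integer.max - 1L, count)
    .render_events(
      onsets = onsets, template = spec$syllable, voice = spec$voice,
      phrase = spec$phrase,
      subphase = .subphase_tags(count, spec$rate_trend),
      rate_hz = rate_hz, seeds = syl_seeds
    )
  })
}

.phrase_onsets <- function(count, rate, trend, cv) {
  if (count == 1L) return(0)
  k <- count - 1L
  mult <- if (k == 1L) 1 else seq(trend, 2 - trend, length.out = k)
  dt <- 1 / (rate * mult)
  if (cv > 0) {
    fac <- 1 + pmax(pmin(rnorm(k, 0, cv), 3 * cv), -3 * cv)
    dt <- dt * fac
  }
  c(0, cumsum(dt))
}

.subphase_tags <- function(count, trend) {
  if (trend == 1) return(rep(NA_character_, count))
  half <- ceiling(count / 2)
  c(rep("cresc", half), rep("decresc", count - half))
}

## Shared renderer: place syllables at given onsets into one buffer.
.render_events <- function(onsets, template, voice, phrase, subphase,
                           rate_hz, seeds) {
  count <- length(onsets)
  durs <- numeric(count)
  waves <- vector("list", count)
  for (i in seq_len(count)) {
    s <- render_syllable(template, rate_hz, seed = seeds[i])
    waves[[i]] <- s$samples
    durs[i] <- duration(s)
  }
  total <- max(onsets + durs) + 0.01
  buf <- numeric(ceiling(total * rate_hz))
  for (i in seq_len(count)) {
    i0 <- round(onsets[i] * rate_hz) + 1L
    idx <- i0:(i0 + length(waves[[i]]) - 1L)
    buf[idx] <- buf[idx] + waves[[i]]
  }
  events <- annotation_track(
    onset = onsets, offset = onsets + durs,
    sex = rep(voice, count), phrase = rep(phrase, count),
    syllable = rep(template$name, count), subphase = subphase
  )
  list(signal = audio_signal(buf, rate_hz), events = events)
}

#' Add background noise at a target signal-to-noise ratio
#'
#' `kind = "insect_band"` confines the noise to the 6-7 kHz band typical of
#' insect choruses in field recordings; `"broadband"` is white noise.  The
#' noise is scaled so that the signal-to-noise power ratio equals `snr_db`.
#' `snr_db = Inf` is the no-noise sentinel and returns the signal unchanged.
#'
#' @param signal A mono [audio_signal()].
#' @param kind `"insect_band"` or `"broadband"`.
#' @param snr_db Target SNR in dB (finite, or `Inf` for none).
#' @param seed Integer seed.
#' @return An [audio_signal()] with noise added.
#' @export
add_background <- function(signal, kind = c("insect_band", "broadband"),
                           snr_db = 10, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(signal, "audio_signal"))
  if (is.infinite(snr_db) && snr_db > 0) return(signal)
  if (!is.finite(snr_db)) stop("snr_db must be finite (or +Inf for none)", call. = FALSE)
  n <- n_samples(signal)
  with_rng_seed(seed, {
    noise <- if (kind == "insect_band") {
      if (signal$rate / 2 <= 7000) {
        stop("insect-band noise needs a sampling rate above 14 kHz", call. = FALSE)
      }
      .bandlimited_noise(n, signal$rate, 6000, 7000)
    } else {
      rnorm(n)
    }
    sig_pow <- mean(signal$samples^2)
    noise <- noise / sqrt(mean(noise^2)) * sqrt(sig_pow / 10^(snr_db / 10))
    audio_signal(signal$samples + noise, signal$rate, signal$bit_depth)
  })
}
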