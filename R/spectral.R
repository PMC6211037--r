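## Spectral features of the combined (both-voice) duet signal.
##
## The mean power spectrum averages squared-magnitude Hann-windowed FFTs
## over non-overlapping 2048-sample windows and is max-normalized
## ("relative amplitude"); the cumulative spectrum is the running band
## energy normalized to 1 at the band top.  The dominant frequency is the
## largest of the five largest local maxima inside the 80-2000 Hz analysis
## band; the halfway frequency is where the cumulative curve crosses 0.5.

#' Mean power spectrum (Welch, non-overlapping Hann windows)
#'
#' @param signal A mono [audio_signal()] with at least `window` samples.
#' @param window Window length in samples (default 2048); a trailing
#'   partial window is discarded.
#' @return A `power_spectrum`: list with `frequencies` (Hz, spacing
#'   `rate / window`) and `power` (max-normalized mean squared magnitude).
#' @export
mean_power_spectrum <- function(signal, window = 2048L) {
  stopifnot(inherits(signal, "audio_signal"))
  if (n_channels(signal) != 1L) stop("spectrum of a mono signal only", call. = FALSE)
  x <- signal$samples
  n <- length(x)
  if (n < window) {
    stop(sprintf("signal too short: %d samples < window %d", n, window),
         call. = FALSE)
  }
  nwin <- n %/% window
  h <- 0.5 * (1 - cos(2 * pi * (seq_len(window) - 1) / window))  # Hann
  acc <- numeric(window %/% 2 + 1L)
  for (w in seq_len(nwin)) {
    seg <- x[((w - 1L) * window + 1L):(w * window)] * h
    sp <- Mod(fft(seg))^2
    acc <- acc + sp[seq_len(window %/% 2 + 1L)]
  }
  pw <- acc / nwin
  if (max(pw) > 0) pw <- pw / max(pw)
  structure(
    list(frequencies = (seq_len(window %/% 2 + 1L) - 1L) * signal$rate / window,
         power = pw, rate = signal$rate, window = as.integer(window)),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %.2f Hz resolution, 0-%.0f Hz\n",
              length(x$power), x$frequencies[2L], max(x$frequencies)))
  invisible(x)
}

## Indices of strict local maxima; a plateau is represented by its
## lowest-frequency bin.
.local_maxima <- function(p) {
  n <- length(p)
  if (n < 3L) return(integer())
  idx <- integer()
  i <- 2L
  while (i < n) {
    if (p[i] > p[i - 1L]) {
      j <- i
      while (j < n && p[j + 1L] == p[j]) j <- j + 1L  # walk a plateau
      if (j < n && p[j + 1L] < p[j]) idx <- c(idx, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  idx
}

#' Spectral peaks and dominant frequency
#'
#' Finds the five largest local maxima of the spectrum inside `band` and
#' returns the largest as the dominant frequency.  Ties between equal-power
#' peaks are broken toward the lower frequency.
#'
#' @param spectrum A [mean_power_spectrum()] result.
#' @param band Two-element Hz interval to search (default `c(80, 2000)`).
#' @param n_peaks Number of peaks to retain (default 5).
#' @return For [spectral_peaks()], a data frame (frequency, power, rank);
#'   for [dominant_frequency()], the dominant frequency in Hz.
#' @export
spectral_peaks <- function(spectrum, band = c(80, 2000), n_peaks = 5L) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  sel <- spectrum$frequencies >= band[1L] & spectrum$frequencies <= band[2L]
  if (!any(sel)) stop("band outside the spectrum grid", call. = FALSE)
  f <- spectrum$frequencies[sel]
  p <- spectrum$power[sel]
  lm <- .local_maxima(p)
  if (!length(lm)) {
    stop(sprintf("no local maximum in band [%g, %g] Hz", band[1L], band[2L]),
         call. = FALSE)
  }
  ord <- order(-p[lm], f[lm])  # power desc, frequency asc on ties
  keep <- lm[ord][seq_len(min(n_peaks, length(lm)))]
  data.frame(frequency = f[keep], power = p[keep],
             rank = seq_along(keep))
}

#' @rdname spectral_peaks
#' @export
dominant_frequency <- function(spectrum, band = c(80, 2000), n_peaks = 5L) {
  spectral_peaks(spectrum, band, n_peaks)$frequency[1L]
}

#' Cumulative spectral energy distribution over a band
#'
#' @param spectrum A [mean_power_spectrum()] result.
#' @param band Hz interval (default `c(80, 2000)`).
#' @return A `cumulative_spectrum`: list with `frequencies` and
#'   `cumulative` (non-decreasing, ending exactly at 1).
#' @export
cumulative_distribution <- function(spectrum, band = c(80, 2000)) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  sel <- spectrum$frequencies >= band[1L] & spectrum$frequencies <= band[2L]
  p <- spectrum$power[sel]
  tot <- sum(p)
  if (tot <= 0) stop("zero band energy; cannot form a cumulative curve", call. = FALSE)
  structure(
    list(frequencies = spectrum$frequencies[sel], cumulative = cumsum(p) / tot),
    class = "cumulative_spectrum"
  )
}

#' Halfway frequency of a cumulative spectrum
#'
#' The frequency at which the cumulative band-energy curve crosses 0.5,
#' linearly interpolated between bins.  Invariant to overall spectrum gain.
#'
#' @param cum A [cumulative_distribution()] result.
#' @return Frequency in Hz.
#' @export
halfway_frequency <- function(cum) {
  stopifnot(inherits(cum, "cumulative_spectrum"))
  f <- cum$frequencies
  y <- cum$cumulative
  i <- which(y >= 0.5)[1L]
  if (i == 1L) return(f[1L])
  f[i - 1L] + (0.5 - y[i - 1L]) / (y[i] - y[i - 1L]) * (f[i] - f[i - 1L])
}

#' Mean and SEM of a set of power spectra
#'
#' @param spectra List of [mean_power_spectrum()] results on identical
#'   frequency grids.
#' @return List with `frequencies`, `mean`, `sem` (zero when `n = 1`,
#'   with `sem_defined = FALSE`), and `n`.
#' @export
group_mean_spectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  f0 <- spectra[[1L]]$frequencies
  for (s in spectra) {
    if (!isTRUE(all.equal(s$frequencies, f0))) {
      stop("spectra are on different frequency grids", call. = FALSE)
    }
  }
  m <- vapply(spectra, `[[`, numeric(length(f0)), "power")
  m <- matrix(m, nrow = length(f0))
  n <- ncol(m)
  mu <- rowMeans(m)
  sem <- if (n > 1L) apply(m, 1L, sd) / sqrt(n) else numeric(length(f0))
  list(frequencies = f0, mean = mu, sem = sem, n = n, sem_defined = n > 1L)
}

#' Per-pair bellow spectrum for the sex-difference comparison
#'
#' Concatenates the annotated bellow segments of one voice (each segment
#' carries whatever the partner overlaps, typically soft pants) and
#' computes the mean power spectrum of the concatenation; the dominant
#' frequency of that spectrum is the comparison statistic.
#'
#' @param signal A mono [audio_signal()].
#' @param track An [annotation_track()] containing bellow events for the
#'   requested voice.
#' @param bellow_voice `"m"` or `"f"`: whose bellows to extract.
#' @param window FFT window length.
#' @return A `power_spectrum` of the concatenated bellow segments.
#' @export
pair_bellow_spectrum <- function(signal, track, bellow_voice = c("m", "f"),
                                 window = 2048L) {
  bellow_voice <- match.arg(bellow_voice)
  stopifnot(inherits(signal, "audio_signal"), inherits(track, "annotation_track"))
  ev <- track[track$sex == bellow_voice & track$syllable == "bellow", , drop = FALSE]
  if (!nrow(ev)) {
    stop("no bellow events for voice '", bellow_voice, "' in the track",
         call. = FALSE)
  }
  segs <- lapply(seq_len(nrow(ev)), function(i) {
    i0 <- max(1L, round(ev$onset[i] * signal$rate) + 1L)
    i1 <- min(n_samples(signal), round(ev$offset[i] * signal$rate))
    signal$samples[i0:i1]
  })
  mean_power_spectrum(audio_signal(unlist(segs), signal$rate), window = window)
}
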