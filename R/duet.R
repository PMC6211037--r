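## Assemble whole duets from a species profile: draw per-sequence periods
## around the profile's sequence-duration target, schedule every grammar
## phrase inside each sequence, render, and mix the two voices into one
## buffer.  The ground truth records exactly one annotation per rendered
## syllable plus the realized sequence starts and periods.

#' Synthesize an annotated duet
#'
#' @param profile A [species_profile()].
#' @param n_sequences Number of duet sequences to generate (>= 1).
#' @param rate_hz Sampling rate in Hz.
#' @param seed Integer seed; fixed seed gives bit-identical waveform and
#'   ground truth.
#' @return A list with
#'   \describe{
#'     \item{signal}{mono [audio_signal()] of the mixed duet}
#'     \item{truth}{list with `track` (an [annotation_track()]),
#'       `sequence_starts` (s), `periods` (realized per-sequence durations,
#'       s), and `species`}
#'   }
#' @export
#' @examples
#' lib <- profile_library()
#' duet <- synthesize_duet(lib$donacophilus, n_sequences = 2, seed = 7)
#' duet$signal
synthesize_duet <- function(profile, n_sequences, rate_hz = 44100, seed = 1L) {
  stopifnot(inherits(profile, "species_profile"), n_sequences >= 1)
  grammar <- profile$grammar
  with_rng_seed(seed, {
    cv <- profile$jitter_cv
    periods <- grammar$period *
      (1 + pmax(pmin(rnorm(n_sequences, 0, cv), 3 * cv), -3 * cv))
    starts <- c(0, cumsum(periods))[seq_len(n_sequences)]
    phrase_seeds <- matrix(
      sample.int(.Machine$integer.max - 1L, n_sequences * length(grammar$entries)),
      nrow = n_sequences
    )
    pieces <- list()
    events <- list()
    k <- 0L
    for (s in seq_len(n_sequences)) {
      for (e in seq_along(grammar$entries)) {
        entry <- grammar$entries[[e]]
        ph <- build_phrase(entry$spec, rate_hz, seed = phrase_seeds[s, e])
        t0 <- starts[s] + entry$offset_frac * periods[s]
        k <- k + 1L
        pieces[[k]] <- list(start = t0, samples = ph$signal$samples)
        ev <- ph$events
        ev$onset <- ev$onset + t0
        ev$offset <- ev$offset + t0
        events[[k]] <- as.data.frame(ev)
      }
    }
    total_s <- max(vapply(pieces, function(p) p$start + length(p$samples) / rate_hz,
                          0)) + 0.05
    buf <- numeric(ceiling(total_s * rate_hz))
    for (p in pieces) {
      i0 <- round(p$start * rate_hz) + 1L
      idx <- i0:(i0 + length(p$samples) - 1L)
      buf[idx] <- buf[idx] + p$samples
    }
    ev <- do.call(rbind, events)
    track <- annotation_track(ev$onset, ev$offset, ev$sex, ev$phrase,
                              ev$syllable, ev$subphase)
    list(
      signal = audio_signal(buf / max(abs(buf)) * 0.9, rate_hz),
      truth = list(track = track, sequence_starts = starts,
                   periods = periods, species = profile$species)
    )
  })
}

#' Write a synthesized duet to disk
#'
#' Writes the waveform as 16-bit PCM WAV and the annotations as an
#' Audacity label-track TSV next to it.
#'
#' @param duet Result of [synthesize_duet()].
#' @param wav_path Output WAV path; the label file gets the same stem with
#'   a `.txt` extension.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_duet <- function(duet, wav_path) {
  write_wav(duet$signal, wav_path)
  label_path <- sub("\\.wav$", ".txt", wav_path, ignore.case = TRUE)
  if (identical(label_path, wav_path)) label_path <- paste0(wav_path, ".txt")
  write_labels(duet$truth$track, label_path)
  invisible(c(wav = wav_path, labels = label_path))
}
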