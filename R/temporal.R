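## Temporal features: duet sequence segmentation and call-rate statistics.
##
## A "male duet sequence" runs from the first syllable of one male pant
## phrase to the first syllable of the next male pant phrase; the final
## unbounded interval is discarded.  Call rate within a phrase is
## (number of syllables - 1) / (last onset - first onset).

## Group a voice's annotation events into phrase instances: consecutive
## events with the same (sex, phrase) whose onset gap does not exceed
## `max_gap` seconds form one instance.
.phrase_instances <- function(track, max_gap = 1.5) {
  stopifnot(inherits(track, "annotation_track"))
  df <- as.data.frame(track)
  df <- df[order(df$sex, df$phrase, df$onset), , drop = FALSE]
  out <- list()
  for (key in unique(paste(df$sex, df$phrase, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- df[df$sex == parts[1L] & df$phrase == parts[2L], , drop = FALSE]
    gaps <- c(Inf, diff(sub$onset))
    sub$instance <- cumsum(gaps > max_gap)
    out[[key]] <- sub
  }
  res <- do.call(rbind, out)
  res <- res[order(res$onset), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Segment a duet into male-pant-delimited sequences
#'
#' Sequence boundaries are the first onsets of successive male pant
#' phrases; the trailing unbounded interval is discarded, so a track with
#' `k` male pant phrase starts yields `k - 1` sequences.
#'
#' @param track An [annotation_track()] with at least two male pant phrase
#'   onsets.
#' @param max_gap Largest onset gap (s) joining events into one phrase
#'   instance.
#' @return Data frame with one row per sequence: `start`, `end`,
#'   `duration` (s), `n_events` contained.
#' @export
segment_sequences <- function(track, max_gap = 1.5) {
  inst <- .phrase_instances(track, max_gap)
  pant_m <- inst[inst$sex == "m" & inst$phrase == "pant", , drop = FALSE]
  if (!nrow(pant_m)) stop("no male pant phrases in the track", call. = FALSE)
  starts <- tapply(pant_m$onset, pant_m$instance, min)
  starts <- sort(unname(starts))
  if (length(starts) < 2L) {
    stop("need at least two male pant phrase onsets to delimit a sequence",
         call. = FALSE)
  }
  k <- length(starts) - 1L
  data.frame(
    start = starts[seq_len(k)],
    end = starts[seq_len(k) + 1L],
    duration = diff(starts),
    n_events = vapply(seq_len(k), function(i) {
      sum(track$onset >= starts[i] & track$onset < starts[i + 1L])
    }, 0L)
  )
}

#' Call rate of a run of onsets
#'
#' `(n - 1) / (last onset - first onset)` for `n` strictly increasing
#' onsets.  Invariant under time translation; scaling time by `k` divides
#' the rate by `k`.
#'
#' @param onsets Strictly increasing onset times in seconds (length >= 2).
#' @return Rate in calls/s.
#' @export
call_rate <- function(onsets) {
  if (length(onsets) < 2L) {
    stop("call rate is undefined for fewer than two onsets", call. = FALSE)
  }
  if (any(diff(onsets) <= 0)) {
    stop("onsets must be strictly increasing", call. = FALSE)
  }
  (length(onsets) - 1) / (onsets[length(onsets)] - onsets[1L])
}

#' Per-phrase call rates of one phrase type
#'
#' Computes one [call_rate()] per phrase instance of the requested type.
#' `"rhythmic"` phrases (the donacophilus-group analogue of pumping) are
#' aliased to `"pump"`, so requesting pump rates includes them.
#' Single-syllable instances are skipped with a warning.
#'
#' @param track An [annotation_track()].
#' @param phrase Phrase type: `"pant"`, `"bellow"`, `"pump"`, `"rhythmic"`, ...
#' @param sex Optional voice filter (`"m"`/`"f"`).
#' @param max_gap Phrase-instance grouping gap in seconds.
#' @return Numeric vector of rates (possibly empty, with a warning).
#' @export
phrase_rates <- function(track, phrase, sex = NULL, max_gap = 1.5) {
  inst <- .phrase_instances(track, max_gap)
  wanted <- if (phrase == "pump") c("pump", "rhythmic") else phrase
  sel <- inst$phrase %in% wanted
  if (!is.null(sex)) sel <- sel & inst$sex %in% sex
  sub <- inst[sel, , drop = FALSE]
  if (!nrow(sub)) {
    warning("no '", phrase, "' phrases found", call. = FALSE)
    return(numeric())
  }
  keys <- paste(sub$sex, sub$phrase, sub$instance)
  rates <- vapply(split(sub$onset, keys), function(on) {
    if (length(on) < 2L) NA_real_ else call_rate(sort(on))
  }, 0)
  if (anyNA(rates)) {
    warning(sum(is.na(rates)), " single-syllable phrase(s) skipped", call. = FALSE)
  }
  ord <- vapply(split(sub$onset, keys), min, 0)
  unname(rates[order(ord)][!is.na(rates[order(ord)])])
}

#' Crescendo vs decrescendo bellow rates per sequence
#'
#' For each duet sequence, computes the bellow call rate separately over
#' the crescendo-tagged and decrescendo-tagged bellow syllables of the
#' male bellow phrase.  The paired differences feed the exact signed-rank
#' test.
#'
#' @param track An [annotation_track()] whose bellow events carry
#'   `"cresc"`/`"decresc"` sub-phase tags.
#' @param sex Voice whose bellow phrases to use (default `"m"`).
#' @param max_gap Phrase grouping gap in seconds.
#' @return Data frame with one row per bellow phrase: `crescendo_rate`,
#'   `decrescendo_rate` (calls/s).
#' @export
crescendo_decrescendo_rates <- function(track, sex = "m", max_gap = 1.5) {
  inst <- .phrase_instances(track, max_gap)
  sub <- inst[inst$sex == sex & inst$phrase == "bellow", , drop = FALSE]
  if (!nrow(sub)) stop("no bellow phrases for voice '", sex, "'", call. = FALSE)
  if (all(is.na(sub$subphase))) {
    stop("bellow events carry no crescendo/decrescendo sub-phase tags; ",
         "annotate the phases (label syntax sex:phrase:syllable:subphase)",
         call. = FALSE)
  }
  res <- lapply(split(sub, sub$instance), function(g) {
    cr <- sort(g$onset[g$subphase %in% "cresc"])
    de <- sort(g$onset[g$subphase %in% "decresc"])
    if (length(cr) < 2L || length(de) < 2L) return(NULL)
    data.frame(crescendo_rate = call_rate(cr), decrescendo_rate = call_rate(de))
  })
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out) || !nrow(out)) {
    stop("no bellow phrase had at least two syllables in each sub-phase",
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Extract the three duet features from one recording
#'
#' Runs the standard chain: preprocessing (mono, 44.1 kHz, 80 Hz
#' high-pass, peak normalization), 2 kHz low-pass, mean power spectrum,
#' dominant frequency in 80-2000 Hz; sequence durations from the
#' male-pant segmentation; pant call rate per pant phrase.  Duration and
#' rate are averaged per duet (the duet is the sampling unit).
#'
#' @param signal An [audio_signal()].
#' @param track The matching [annotation_track()].
#' @param band Dominant-frequency search band in Hz.
#' @param preprocess Whether to apply [preprocess_audio()] first.
#' @return List with `dominant_frequency` (Hz), `sequence_duration` (s,
#'   mean), `pant_rate` (calls/s, mean), and the per-sequence detail.
#' @export
features_from_duet <- function(signal, track, band = c(80, 2000),
                               preprocess = TRUE) {
  s <- if (preprocess) preprocess_audio(signal) else to_mono(signal)
  lp <- bandpass_chain(s, high_pass = NULL, low_pass = 2000)
  spec <- mean_power_spectrum(lp)
  segs <- segment_sequences(track)
  rates <- phrase_rates(track, "pant")
  list(
    dominant_frequency = dominant_frequency(spec, band),
    sequence_duration = mean(segs$duration),
    pant_rate = mean(rates),
    sequences = segs, pant_rates = rates, spectrum = spec
  )
}

#' Assemble the per-duet feature table
#'
#' One row per duet recording (one duet per family group; duplicated group
#' ids are rejected as pseudoreplication).  Rows with a failed feature are
#' excluded with a message.
#'
#' @param duets List of lists, each with `signal`, `track`, and metadata
#'   fields `group`, `species`, `lineage`.
#' @param preprocess Passed to [features_from_duet()].
#' @return Data frame with columns `group`, `species`, `lineage`,
#'   `dom_freq_hz`, `seq_dur_s`, `pant_rate_cps`.
#' @export
assemble_feature_table <- function(duets, preprocess = TRUE) {
  groups <- vapply(duets, function(d) as.character(d$group), "")
  if (anyDuplicated(groups)) {
    stop("duplicate duet for group(s): ",
         paste(unique(groups[duplicated(groups)]), collapse = ", "),
         " (one duet per group)", call. = FALSE)
  }
  rows <- lapply(duets, function(d) {
    feats <- tryCatch(
      features_from_duet(d$signal, d$track, preprocess = preprocess),
      error = function(e) {
        message("excluding group ", d$group, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(feats)) return(NULL)
    data.frame(
      group = as.character(d$group), species = as.character(d$species),
      lineage = as.character(d$lineage),
      dom_freq_hz = feats$dominant_frequency,
      seq_dur_s = feats$sequence_duration,
      pant_rate_cps = feats$pant_rate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
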