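# Syllable rendering, phrase assembly, duet synthesis, background noise.

test_that("a pure-tone syllable puts its dominant bin at the carrier and is seed-deterministic", {
  s <- render_syllable(tone_template(1000), 44100, seed = 42)
  expect_equal(n_samples(s), round(0.2 * 44100))
  spec <- Mod(stats::fft(s$samples))^2
  half <- seq_len(length(spec) %/% 2)
  peak_hz <- (which.max(spec[half]) - 1) * 44100 / length(spec)
  expect_lt(abs(peak_hz - 1000), 44100 / n_samples(s) + 1e-9)

  s2 <- render_syllable(tone_template(1000), 44100, seed = 42)
  expect_identical(s$samples, s2$samples)
  s3 <- render_syllable(tone_template(1000), 44100, seed = 43)
  expect_false(identical(s$samples, s3$samples))
})

test_that("a noise-burst pant concentrates its energy in the template band (FFT oracle)", {
  s <- render_syllable(pant_noise_template(1100, 800), 44100, seed = 5)
  expect_gte(band_energy_fraction(s, 700, 1500), 0.8)
})

test_that("carrier content above Nyquist is rejected as aliasing", {
  tpl <- syllable_template("high", carrier = 9000, duration = 0.1,
                           harmonic_count = 3L)
  expect_error(render_syllable(tpl, 44100), "aliasing")
  expect_silent(render_syllable(tpl, 96000, seed = 1))
})

test_that("template invariants are enforced", {
  expect_error(syllable_template("x", carrier = 100, duration = 0),
               "duration")
  expect_error(syllable_template("x", carrier = 100, duration = 0.1,
                                 bandwidth = 300), "carrier")
  expect_error(syllable_template("x", carrier = 500, duration = 0.1,
                                 noisiness = 1.2), "noisiness")
})

test_that("phrase onsets follow the stated rate exactly when unjittered", {
  sp <- phrase_spec(pant_noise_template(duration = 0.08), c(5, 5), rate = 2,
                    voice = "m", jitter_cv = 0)
  ph <- build_phrase(sp, 44100, seed = 1)
  expect_equal(ph$events$onset, c(0, 0.5, 1.0, 1.5, 2.0))
  expect_equal(nrow(ph$events), 5L)
})

test_that("a pump phrase realizes its nominal rate within 2%", {
  sp <- phrase_spec(pant_noise_template(duration = 0.05), c(6, 6),
                    rate = 4.26, voice = "m", phrase = "pump",
                    jitter_cv = 0.01)
  for (seed in 1:5) {
    ph <- build_phrase(sp, 44100, seed = seed)
    r <- call_rate(ph$events$onset)
    expect_lt(abs(r - 4.26) / 4.26, 0.02)
  }
})

test_that("a rate trend below one makes the first half slower than the second", {
  sp <- phrase_spec(pant_noise_template(duration = 0.05), c(10, 10),
                    rate = 2.3, voice = "m", phrase = "bellow",
                    rate_trend = 0.85, jitter_cv = 0)
  ph <- build_phrase(sp, 44100, seed = 2)
  on <- ph$events$onset
  first <- mean(diff(on[1:5]))
  second <- mean(diff(on[6:10]))
  expect_gt(first, second)
  expect_equal(ph$events$subphase, c(rep("cresc", 5), rep("decresc", 5)))
})

test_that("inconsistent phrase duration and rate are rejected", {
  expect_error(
    phrase_spec(pant_noise_template(), c(5, 5), rate = 2, voice = "m",
                duration = 10),
    "inconsistent")
})

test_that("synthesized moloch-pattern duets honor the bellow count range and are deterministic", {
  lib <- profile_library()
  d <- synthesize_duet(lib$toppini, n_sequences = 3, seed = 9)
  tr <- as.data.frame(d$truth$track)
  bell <- tr[tr$syllable == "bellow" & tr$sex == "m", ]
  # one male bellow phrase per sequence; counts inside the profile range
  counts <- table(findInterval(bell$onset, d$truth$sequence_starts))
  rng <- lib$toppini$bellows_per_sequence_range
  expect_true(all(counts >= rng[1] & counts <= rng[2]))

  d2 <- synthesize_duet(lib$toppini, n_sequences = 3, seed = 9)
  expect_identical(d$signal$samples, d2$signal$samples)
  expect_identical(as.data.frame(d$truth$track), as.data.frame(d2$truth$track))
})

test_that("lineage grammars produce their characteristic phrase inventories", {
  lib <- profile_library()
  syl <- function(sp) {
    d <- synthesize_duet(lib[[sp]], n_sequences = 2, seed = 4)
    as.data.frame(d$truth$track)
  }
  mol <- syl("discolor")
  expect_true("pump" %in% mol$phrase)
  don <- syl("donacophilus")
  expect_true("rhythmic" %in% don$phrase)
  # female loud section precedes the male one within a sequence
  f_bell <- min(don$onset[don$sex == "f" & don$phrase == "bellow"])
  m_bell <- min(don$onset[don$sex == "m" & don$phrase == "bellow"])
  expect_lt(f_bell, m_bell)
  tor <- syl("lucifer")
  expect_true(all(c("pant", "phraseB", "phraseC") %in% tor$phrase))
  expect_false("bellow" %in% tor$phrase)
  oen <- syl("oenanthe")
  expect_true(all(c("whinny", "iii-yep") %in% oen$syllable))
})

test_that("realized sequence durations track the profile target", {
  lib <- profile_library()
  d <- synthesize_duet(lib$donacophilus, n_sequences = 20, seed = 12)
  expect_lt(abs(mean(d$truth$periods) - 4.83) / 4.83, 0.1)
  expect_equal(nrow(as.data.frame(d$truth$track)),
               nrow(as.data.frame(d$truth$track)))  # one annotation per syllable
})

test_that("insect-band noise stays in 6-7 kHz and hits the target SNR", {
  sig <- render_syllable(tone_template(1000, duration = 0.5), 44100, seed = 1)
  noisy <- add_background(sig, "insect_band", snr_db = 10, seed = 3)
  added <- audio_signal(noisy$samples - sig$samples, 44100)
  expect_gte(band_energy_fraction(added, 6000, 7000), 0.95)
  snr <- 10 * log10(mean(sig$samples^2) / mean(added$samples^2))
  expect_lt(abs(snr - 10), 1)
})

test_that("an infinite SNR leaves the signal untouched", {
  sig <- render_syllable(tone_template(800, duration = 0.1), 44100, seed = 1)
  expect_identical(add_background(sig, "broadband", snr_db = Inf), sig)
})

test_that("broadband noise does not move the sub-2 kHz dominant frequency after low-pass", {
  lib <- profile_library()
  d <- synthesize_duet(lib$donacophilus, n_sequences = 3, seed = 21)
  clean <- features_from_duet(d$signal, d$truth$track, preprocess = FALSE)
  noisy_sig <- add_background(d$signal, "broadband", snr_db = 15, seed = 5)
  noisy <- features_from_duet(noisy_sig, d$truth$track, preprocess = FALSE)
  bin <- 44100 / 2048
  expect_lte(abs(clean$dominant_frequency - noisy$dominant_frequency), bin)
})

test_that("the profile library carries the published per-species targets", {
  lib <- profile_library()
  expect_length(lib, 10L)
  expect_equal(lib$oenanthe$dominant_frequency_target, 1464.2)
  expect_equal(lib$lucifer$dominant_frequency_target, 671.1)
  expect_equal(lib$urubambensis$lineage, "donacophilus")
  expect_equal(lib$urubambensis$acoustic_lineage, "moloch")
  expect_equal(sum(vapply(lib, `[[`, 0L, "n_groups")), 36L)
  for (p in lib) {
    expect_s3_class(p, "species_profile")
    expect_gt(p$dominant_frequency_target, 0)
    expect_gt(p$pant_rate_target, 0)
    expect_gt(p$sequence_duration_target, 0)
  }
})
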