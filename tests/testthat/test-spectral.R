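# Power spectra, dominant frequency, cumulative curves, pair spectra.

# Synthetic spectrum helper: power_spectrum on an exact-bin grid.
make_spectrum <- function(power, rate = 40960, window = 2048L) {
  structure(
    list(frequencies = (seq_along(power) - 1) * rate / window,
         power = power / max(power), rate = rate, window = window),
    class = "power_spectrum"
  )
}

test_that("mean power spectrum localizes a tone and reproduces analytic power ratios", {
  t44 <- seq_len(44100) / 44100
  tone <- audio_signal(sin(2 * pi * 1000 * t44), 44100)
  sp <- mean_power_spectrum(tone)
  expect_lt(abs(dominant_frequency(sp) - 1000), 44100 / 2048)

  fs <- 40960  # 20 Hz bins: 600 and 1200 Hz fall exactly on bins
  t <- seq_len(fs) / fs
  two <- audio_signal(sin(2 * pi * 600 * t) + 0.5 * sin(2 * pi * 1200 * t), fs)
  sp2 <- mean_power_spectrum(two)
  i600 <- which.min(abs(sp2$frequencies - 600))
  i1200 <- which.min(abs(sp2$frequencies - 1200))
  expect_equal(sp2$power[i1200] / sp2$power[i600], 0.25, tolerance = 1e-3)
  expect_equal(max(sp2$power), 1)

  expect_error(mean_power_spectrum(audio_signal(numeric(100), fs)), "short")
})

test_that("averaging more windows shrinks the per-bin noise variability", {
  fs <- 44100
  cv_of <- function(n_win, seed) {
    x <- withr::with_seed(seed, stats::rnorm(2048 * n_win))
    sp <- mean_power_spectrum(audio_signal(x / max(abs(x)), fs))
    sel <- sp$frequencies > 200 & sp$frequencies < 20000
    stats::sd(sp$power[sel]) / mean(sp$power[sel])
  }
  expect_lt(cv_of(100, 1), cv_of(10, 2))
})

test_that("dominant frequency picks the largest local maximum with low-frequency tie-break", {
  # peaks at bins for 500 Hz (0.6) and 1000 Hz (1.0)
  p <- rep(0.01, 120)
  p[26] <- 0.6   # 25*20 = 500 Hz
  p[51] <- 1.0   # 1000 Hz
  sp <- make_spectrum(p)
  expect_equal(dominant_frequency(sp), 1000)
  pk <- spectral_peaks(sp)
  expect_equal(pk$rank, seq_len(nrow(pk)))
  expect_true(all(diff(pk$power) <= 0))

  # two equal peaks: tie broken toward the lower frequency
  p[26] <- 1.0
  expect_equal(dominant_frequency(make_spectrum(p)), 500)

  flat <- make_spectrum(rep(0.5, 120))
  expect_error(dominant_frequency(flat), "local maximum")
})

test_that("cumulative distributions are monotone, normalized, and match simple shapes", {
  flat <- make_spectrum(rep(1, 120))
  cum <- cumulative_distribution(flat, band = c(80, 2000))
  expect_true(all(diff(cum$cumulative) >= 0))
  expect_equal(max(cum$cumulative), 1)
  # flat spectrum: halfway frequency at the band midpoint
  expect_lt(abs(halfway_frequency(cum) - mean(c(80, 2000))), 25)

  step <- rep(1e-12, 120)
  step[36] <- 1  # 700 Hz
  cs <- cumulative_distribution(make_spectrum(step), band = c(80, 2000))
  expect_lt(abs(halfway_frequency(cs) - 700), 20 + 1e-9)

  zero <- make_spectrum(c(rep(1, 3), rep(0, 117)))  # all power below 80 Hz
  expect_error(cumulative_distribution(zero, band = c(200, 2000)), "zero band")
})

test_that("halfway frequency is invariant to overall spectrum gain", {
  p <- withr::with_seed(3, stats::runif(120, 0.1, 1))
  sp1 <- make_spectrum(p)
  sp2 <- make_spectrum(p * 7)   # max-normalization makes these identical
  expect_equal(halfway_frequency(cumulative_distribution(sp1)),
               halfway_frequency(cumulative_distribution(sp2)))
})

test_that("group mean spectrum matches a direct mean/SEM oracle", {
  sps <- lapply(1:3, function(i) {
    make_spectrum(withr::with_seed(i, stats::runif(64, 0.2, 1)))
  })
  gm <- group_mean_spectrum(sps)
  mat <- sapply(sps, `[[`, "power")
  expect_equal(gm$mean, rowMeans(mat))
  expect_equal(gm$sem, apply(mat, 1, stats::sd) / sqrt(3))

  # identical spectra: SEM zero
  gm3 <- group_mean_spectrum(rep(sps[1], 3))
  expect_equal(gm3$sem, numeric(64))
  # n = 2: SEM = |difference| / 2
  gm2 <- group_mean_spectrum(sps[1:2])
  expect_equal(gm2$sem, abs(mat[, 1] - mat[, 2]) / 2)
  # n = 1 flagged
  expect_false(group_mean_spectrum(sps[1])$sem_defined)

  bad <- make_spectrum(stats::runif(64), rate = 44100)
  expect_error(group_mean_spectrum(list(sps[[1]], bad)), "grids")
})

test_that("female bellow spectra sit above male ones by construction of the sex offset", {
  lib <- profile_library()
  for (seed in c(1, 8)) {
    d <- synthesize_duet(lib$discolor, n_sequences = 3, seed = seed)
    dm <- dominant_frequency(pair_bellow_spectrum(d$signal, d$truth$track, "m"))
    df_ <- dominant_frequency(pair_bellow_spectrum(d$signal, d$truth$track, "f"))
    expect_gt(df_, dm)
  }
})

test_that("a track without the requested voice's bellows is an error", {
  tr <- annotation_track(0.1, 0.2, "m", "bellow", "bellow")
  sig <- audio_signal(numeric(44100), 44100)
  expect_error(pair_bellow_spectrum(sig, tr, "f"), "no bellow")
})

test_that("dominant frequency below 1.5 kHz is unaffected by the 2 kHz low-pass", {
  lib <- profile_library()
  d <- synthesize_duet(lib$donacophilus, n_sequences = 2, seed = 14)
  raw <- mean_power_spectrum(d$signal)
  filt <- mean_power_spectrum(bandpass_chain(d$signal, high_pass = NULL,
                                             low_pass = 2000))
  bin <- 44100 / 2048
  expect_lte(abs(dominant_frequency(raw) - dominant_frequency(filt)), bin)
})

test_that("halfway frequencies order torquatus < moloch across seeds", {
  lib <- profile_library()
  for (seed in c(3, 9)) {
    hw <- function(sp) {
      d <- synthesize_duet(lib[[sp]], n_sequences = 2, seed = seed)
      lp <- bandpass_chain(d$signal, high_pass = NULL, low_pass = 2000)
      halfway_frequency(cumulative_distribution(mean_power_spectrum(lp)))
    }
    expect_lt(hw("lucifer"), hw("toppini"))
  }
})
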