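# Shared fixtures: tiny syllable templates and a band-energy oracle used
# across the synthesis and spectral tests.

tone_template <- function(carrier = 1000, duration = 0.2, amp = 1) {
  syllable_template("tone", carrier = carrier, duration = duration,
                    bandwidth = 0, harmonic_count = 1L, noisiness = 0,
                    amplitude = amp)
}

pant_noise_template <- function(carrier = 1100, bandwidth = 800,
                                duration = 0.2) {
  syllable_template("pant", carrier = carrier, duration = duration,
                    bandwidth = bandwidth, noisiness = 1, amplitude = 1)
}

# Direct FFT oracle: fraction of total spectral energy inside [f_lo, f_hi].
band_energy_fraction <- function(signal, f_lo, f_hi) {
  x <- signal$samples
  sp <- Mod(stats::fft(x))^2
  n <- length(x)
  f <- (seq_len(n) - 1) * signal$rate / n
  f <- pmin(f, signal$rate - f)
  sum(sp[f >= f_lo & f <= f_hi]) / sum(sp)
}

# Raw sample with exactly the requested mean and sd.
sample_with_moments <- function(n, mean, sd, seed = 1L) {
  x <- withr::with_seed(seed, stats::rnorm(n))
  as.vector(scale(x)) * sd + mean
}
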