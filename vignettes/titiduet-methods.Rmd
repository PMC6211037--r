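---
title: "Methods: duet features, synthesis model, and statistical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duet features, synthesis model, and statistical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titiduet)
```

## The analysis problem

Titi monkey pairs duet with near-complete temporal overlap of the two
voices, which defeats source separation. `titiduet` therefore treats the
duet as one combined signal and characterises it by three parameters per
family group — dominant frequency of the combined signal, duet sequence
duration, and pant call rate — and asks how well these separate the major
lineages (donacophilus, moloch, torquatus) under a Fisher linear
discriminant analysis. One duet per family group is the sampling unit
throughout; the package refuses duplicated group ids to guard against
pseudoreplication.

## Acoustic hierarchy and feature definitions

A *syllable* is a continuous spectrographic trace; runs of similar
(typically paired) syllables form a *phrase*; an ordered combination of
phrases forms a *sequence*; sets of sequences form a *bout*. Concretely:

- **Dominant frequency (Hz).** Mean power spectrum over non-overlapping
  2048-sample Hann windows (squared magnitude, averaged, max-normalised;
  at 44.1 kHz the bin width is 21.53 Hz); the trailing partial window is
  discarded. Among the five largest strict local maxima inside 80–2000 Hz,
  the largest is the dominant frequency. Plateaus are represented by their
  lowest-frequency bin and ties between equal-power peaks break toward the
  lower frequency — both rules are deterministic and tested.
- **Sequence duration (s).** Male pant phrases act as sequence markers
  (pants occur in all ten species, unlike bellows): a sequence runs from
  the first syllable of one male pant phrase to the first syllable of the
  next, and the final unbounded interval is discarded, so *k* marker
  onsets yield *k* − 1 durations. Phrase instances are reconstructed from
  the annotations by grouping same-voice, same-type events whose onset
  gaps do not exceed `max_gap` (default 1.5 s — comfortably above the
  0.2–0.7 s within-phrase gaps implied by observed call rates and below
  the several-second spacing between repeats of a phrase type).
- **Pant call rate (calls/s).** Within a phrase of *n* syllables,
  (*n* − 1) divided by the span from first to last onset. Paired
  (inhale–exhale) syllables count individually. Single-syllable phrases
  are skipped with a warning rather than an error.

Per duet, duration and rate are aggregated by the arithmetic mean over
that duet's sequences/phrases; the aggregator is a documented choice (a
median would also be defensible; the mean keeps the summary-statistic
reconstructions exact for Gaussian synthetic data).

Cumulative spectra (running band energy, normalised to 1 at the band top)
summarise spectral placement by the *halfway frequency*, the point where
the curve crosses 0.5, linearly interpolated between bins; it is invariant
to overall gain by construction.

## Preprocessing chain

Recordings are split to mono (default: left channel — a documented
convention, since either channel carries the combined signal), downsampled
to 44.1 kHz when the source rate is higher (polyphase FIR via
`signal::resample`), high-pass filtered at 80 Hz, and peak-normalised to
full scale. For spectral work a 2 kHz low-pass removes bird/insect
contamination. Filters are 4th-order Butterworth applied
forward–backward: the zero-phase response leaves onset timing — which the
temporal features depend on — unshifted, and the squared magnitude gives
roughly 48 dB attenuation one octave below the high-pass cutoff.
Peak-to-full-scale normalisation is the simplest realisation of "the
loudest peak in each file is the same"; any common gain cancels in every
downstream feature.

## The synthetic duet generator

No public corpus of annotated titi duets exists, so the test bed is a
generator whose *defaults are the study conditions*: ten species profiles
(shipped as `inst/extdata/species_profiles.yaml`) whose dominant
frequency, sequence duration, pant rate, pump rate, and bellows-per-phrase
targets equal the published per-species statistics, with

- female bellow carriers offset **+100 Hz** (the published per-pair
  comparisons place female bellow–pant combinations roughly 75–215 Hz
  above male ones);
- loud phrases (bellows, arches, whinnies) **12 dB** above the soft pant
  phrases, mirroring the observation that pants are barely audible under
  the partner's bellows;
- per-interval timing jitter that is truncated Gaussian with **CV 0.05**
  (truncation at 3 CV keeps onsets ordered), and sequence periods jittered
  with the same CV.

Syllable acoustics are deliberately schematic: bellows are 4-harmonic
stacks with slow FM (power rolling off as 1/h³ so the fundamental carries
the peak), pants and terminal elements are band-limited noise bursts,
pumps are short high-rate noisy pulses, arches and whinnies are tonal FM
sweeps, hoots and honks are low narrowband tones. The energy-dominant
syllable class of each profile carries the species' dominant-frequency
target as its carrier, which is what makes the round trip
(synthesis → preprocessing → spectrum → peak picking) a sharp test: the
extracted dominant frequency must land within about one spectral bin of
the target, the pant rate within 5%, and the mean sequence duration
within 10%.

What the generator does *not* emulate — and hence what passing tests do
not establish about field recordings: reverberation and habitat filtering,
distance-dependent attenuation, overlapping neighbour groups, recorder
nonlinearity, individual vocal identity, and annotation error (ground
truth is exact by construction). Optional insect-band noise (band-limited
to 6–7 kHz at a chosen SNR) and broadband noise exercise the robustness of
the sub-2 kHz analysis band, not realism.

All randomness flows from one root seed through named substreams
(`derive_seed`), and every generator function restores the caller's RNG
state, so identical inputs give bit-identical waveforms and annotations.

## Statistical battery

**Reconstruction from printed summaries.** Comparative results are
typically printed as mean ± SEM with *n*; with the group variance
recovered as *n*·SEM², the one-way ANOVA F and the pooled/Welch *t* are
exact functions of the summaries and must agree with the raw-data tests to
numerical precision (the suite asserts 1e-10 relative agreement, and
F = t² for two groups). Comparisons against printed statistics carry a 1%
relative tolerance because the inputs are rounded to 3–4 significant
figures.

**Exact signed-rank test.** The null distribution of V is built by
convolution over rank generating functions — each rank r contributes a
factor (1 + z^r)/2 — which equals full enumeration of the 2^n sign
assignments (asserted against enumeration up to n = 12). The exact path is
used for n ≤ 25; beyond that a normal approximation with continuity
correction takes over. Zero differences are dropped with a warning; the
distribution is symmetric, so p(V) = p(n(n+1)/2 − V). With every paired
difference sharing one sign, V = 0 and the two-sided p is exactly
2/2^n: 0.0078125 at n = 8, 0.015625 at n = 7.

**Rank-based tests.** The rank-sum statistic is reported in the
Mann–Whitney convention (rank sum minus its minimum), so complete
separation gives W = 0. Fully tied data (no evidence either way) returns
p = 1 rather than a degenerate approximation. Kruskal–Wallis and
Shapiro–Wilk are delegated to base R; Levene is the classical
mean-centred version (ANOVA on absolute deviations from group means) —
its F approximation is asymptotic, and measurably liberal below ~10
observations per group, so the calibration check runs at 30 per group.

**Random-intercept mixed model.** Repeated per-sequence measurements
within a duet are correlated, so the duet enters as a random intercept
with species as the fixed factor. The fit profiles the single variance
ratio λ = σᵤ²/σₑ² out of the REML criterion: with per-duet covariance
I + λJ, Woodbury reduces all GLS quantities to per-duet sums and the
criterion to a 1-D function of log λ, optimised on [−15, 15] with a
boundary preference for λ → 0 when the likelihood is flat (e.g. one
measurement per duet, where the ratio is unidentified and the fit
collapses to OLS). The fixed factor is tested by Wald chi-squared on the
species contrasts. The suite cross-checks variance components, fixed
effects, and the Wald statistic against `lme4` and verifies 25% recovery
of a 1.56 intercept SD at the study scale (32 duets × 12 measurements).

**MANOVA.** Wilks Λ and the Pillai trace come from the eigenvalues of
W⁻¹B with Rao's and the standard Pillai F approximations; for one
discriminant dimension Pillai = 1 − Λ exactly. Pairwise Pillai tests with
Bonferroni correction serve as post-hocs.

## Discriminant analysis

Features are z-standardised before fitting (the transform is recorded in
the model, and makes scores and confusion matrices invariant to feature
rescaling). Directions are eigenvectors of W⁻¹B ordered by eigenvalue,
scaled so scores have unit pooled within-class variance, and signed so the
first class centroid is non-negative on each axis (reproducible plots).
Priors are proportional to class sizes and the confusion matrix is
resubstitution (no cross-validation is attempted, matching the original
analysis design). With three classes and three features there are exactly
two directions and the proportions of trace sum to one. Degenerate fits
(zero between-class scatter) are flagged rather than failing; singular
within-class scatter raises an error naming the features.

The two-stage design is built into the pipeline: stage 1 follows the
published taxonomy (urubambensis and oenanthe in the donacophilus
lineage); stage 2 reassigns urubambensis to the moloch lineage — its duet
follows the moloch grammar — and excludes oenanthe, whose vocal phenotype
(narrowband whinnies, iii-yep syllables, 4–6 kHz energy, the longest
sequences and fastest panting) fits none of the three lineages.

When raw recordings are unavailable, lineage-level feature vectors are
simulated as independent Gaussians from the published (mean, SEM, n)
summaries with SD = SEM·√n, 35 duets (9 donacophilus / 20 moloch / 6
torquatus). Independence between the three features is a simplification —
in real duets pant rate and dominant frequency are substantially
correlated — which makes the simulation slightly *harder* to separate
than correlated draws concentrated along a lineage axis would be. Under
these conditions the suite measures perfect 35/35 resubstitution in
roughly 19 of every 20 replicates (94–95 of 100 seeds at the suite's
fixed seed), with the majority accuracy over 100 seeds at 100%; the rare
imperfect replicates are single moloch draws landing > 2 SD toward the
donacophilus centroid on two features at once, and per-replicate
assignments agree exactly with `MASS::lda`.

## Problem sizes and runtime choices

Defaults are chosen so a full synthetic study stays interactive on one
CPU: 36 family groups across the ten profiles with 5 sequences per duet
at 44.1 kHz. Sequence counts per duet and sampling rate are configuration
knobs (`pipeline_config`), and the unit tests use 2–6 sequences per duet.
Group counts per species default to the published study design
(7/2/2/1/1/1/8/7/1/6, totalling 36).

## Interfaces

The package's functions are the interface: `run_pipeline()` orchestrates
synth → preprocess → features → stats → LDA with a seed, a config object,
and an output directory (features CSV, JSON report, provenance), and
`verify_paper_targets()` recomputes the headline checks with expected
values and tolerances. A shell entry point was considered and omitted: the
artifact is an R analysis package whose users work from R scripts, and a
wrapper would only duplicate `Rscript -e` around these two calls.
`scripts/acceptance.R` is exactly such a thin wrapper for the verification
quantities.

## Known limitations

- The synthesis model is phenomenological; it reproduces controlled
  spectral/temporal statistics, not titi voices. Conclusions about real
  recordings require real recordings and manual annotation.
- Whether published power spectra are amplitude or squared-amplitude is
  ambiguous ("relative amplitude"); squared magnitude is used. Peak
  locations, orderings, and all rank-based comparisons are insensitive to
  the choice; absolute curve shapes are not.
- Only the Gaussian random-intercept case is implemented for the mixed
  model — no crossed/nested random effects or other families.
- Segmentation and rates rely on annotations (synthetic ground truth or
  label files); there is no automatic syllable detector.
- Blank cells in the published call inventory ("might be present but has
  not been reported") are treated as absent in the grammars; this is a
  modelling convenience, not a biological claim.
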