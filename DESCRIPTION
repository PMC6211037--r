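Package: titiduet
Title: Comparative Acoustic Analysis of Titi Monkey Duet Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative bioacoustic analysis of titi monkey
    (Callicebinae) duets. Generates annotated synthetic duet recordings from
    lineage-specific grammars, preprocesses PCM WAV audio (channel selection,
    resampling, zero-phase band filtering, peak normalization), extracts the
    three classical duet features (dominant frequency of the combined signal,
    duet sequence duration, pant call rate), reconstructs test statistics from
    printed (mean, SEM, n) summaries, provides exact nonparametric tests, a
    random-intercept mixed model, MANOVA, and Fisher linear discriminant
    analysis for classifying duets into lineages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    lme4,
    withr
Config/testthat/edition: 3
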