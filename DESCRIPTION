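Package: rhythmkit
Title: Quantification of Circadian Rhythms in Bioluminescence, Imaging,
    Behaviour and Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying circadian rhythms across the data types of
    a typical suprachiasmatic nucleus (SCN) study: damped-cosine FFT-NLLS
    fitting of ensemble bioluminescence traces with phase-shift, fold-induction,
    amplitude and RMS response metrics; single-cell time-lapse image analysis
    (ROI detection, Rayleigh phase-coherence statistics, centre-of-mass wave
    descriptors); wheel-running actogram analysis (chi-squared periodogram,
    activity onsets and offsets, phase angle of entrainment, re-entrainment
    PS50 and light-pulse phase shifts); and microarray-style expression
    analysis (detection filtering, quantile normalisation, moments-moderated
    t statistics with FDR, and promoter-element enrichment chi-square).
    Includes seeded synthetic-data generators for all four input classes so
    every estimator can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    limma,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
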