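Package: squirm
Title: Characterizing Movement Artifacts in Naturalistic Infant EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing motion-related artifacts in naturalistic
    infant EEG recordings. Provides video-coded annotation validation and
    aggregation, bad-channel rejection and average re-referencing,
    per-condition segment extraction and 1-s epoching, FFT and DPSS
    multitaper spectral estimation with z-normalized power topographies, and
    a within-subject cluster-based sign-flip permutation test over the
    channel-by-frequency plane comparing motion against resting-state power.
    Includes a seeded synthetic-cohort generator (1/f background,
    band-limited oscillatory prominences, injectable motion-artifact
    signatures, bad channels) so the full pipeline can be exercised and
    validated end to end without access to raw infant recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
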