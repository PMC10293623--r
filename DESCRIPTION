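Package: erdspipe
Title: Event-Related Desynchronization/Synchronization Analysis of Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested end-to-end pipeline for event-related
    desynchronization/synchronization (ERD/S) analysis of multichannel EEG
    recorded during motor execution and motor imagery of hand movements.
    Includes a synthetic-cohort generator with known ground-truth band-power
    modulation (band-limited mu and beta rhythms, 1/f background, ocular
    artifacts), a preprocessing chain (spherical-spline channel interpolation,
    average reference, automated ocular-component removal via ICA, zero-phase
    FIR filtering, epoching, peak-to-peak rejection), ERD/S quantification per
    channel, region of interest and time-frequency bin, and mixed
    repeated-measures ANOVA with Greenhouse-Geisser correction and
    Tukey-corrected post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
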