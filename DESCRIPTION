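Package: oculorhythm
Title: Chronotype-Anchored Cosinor Rhythmometry of Ocular Biometry and Melatonin
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing diurnal rhythms of ocular biometry
    (axial length, choroidal and retinal thickness, anterior chamber
    depth, lens thickness, vitreous chamber depth, intraocular pressure)
    and salivary melatonin sampled at epochs anchored to each
    individual's habitual sleep time. Fits fixed-period 24-hour cosinor
    models (individual ordinary least squares and population linear
    mixed models on the sine/cosine basis) to estimate MESOR, amplitude
    and acrophase; derives dim-light melatonin onset analytically from
    the log-scale melatonin cosinor; compares rhythm parameters across
    seasons with circular phase conventions and Holm-adjusted paired
    tests; classifies axial-length growth against month-scaled
    coordinated-growth thresholds; and simulates synthetic cohorts with
    the same hierarchical structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
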