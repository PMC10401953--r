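Package: fpeta
Title: Event-Triggered Analysis of Fiber Photometry Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable pipeline for fiber photometry time series: import of
    tabular and spectrally resolved recordings, linear unmixing of overlapping
    fluorophore emission spectra, photobleaching detrend models, stream
    alignment and filtering transforms, event detection with an expressive
    interval-filter algebra, z-score / delta-F-over-F / robust z-score
    normalization, and event-triggered-average products (aligned traces,
    heatmap matrices, interval summaries). Includes a synthetic-recording
    generator so the whole pipeline can be exercised offline, a session
    save/load container, and a batch command-line front end driven by a
    single YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
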