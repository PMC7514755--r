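Package: netinfodyn
Title: Information Dynamics of Brain-Cardiovascular-Respiratory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear (Gaussian) information dynamics for multivariate
    physiological time series. Extracts synchronous 1 Hz network series
    (RR interval, respiration, pulse arrival time and EEG band powers)
    from raw multi-rate recordings, fits vector autoregressive models,
    computes per-node information measures (entropy, storage, transfer,
    new information) and conditional transfer entropy via state-space
    submodels, tests directed links with nested-regression F-tests, and
    builds cross-subject consensus networks. Includes a synthetic-data
    generator for benchmark VAR networks and physiological-like raw
    recordings so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
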