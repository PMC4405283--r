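Package: remtriad
Title: Relational Event Models for Proximity-Logger Triads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing close-proximity contact data recorded by
    collar-mounted proximity loggers on triads of animals. Raw logger
    records are cleaned, compressed across reciprocal loggers, and turned
    into a time-ordered stream of tie onset and offset events classified by
    their triadic configuration (pair, group, triangle). Observed onsets are
    modelled with an ordinal relational event model: a stratified
    conditional (multinomial) logit over the risk set of potential onsets,
    with history statistics counting prior pair and group events over an
    hourly and a daily window plus an unfamiliarity contrast. Includes a
    bespoke Newton-Raphson maximum-likelihood fitter, a continuous-time
    generative simulator of triad contact processes for validation and
    power studies, and command-line entry points for reproducible
    end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
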