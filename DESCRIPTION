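Package: isoN2O
Title: Source Apportionment and Substrate-Specific Rate Analysis of Euphotic-Zone N2O
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying microbial sources of nitrous oxide (N2O) in the
    oceanic euphotic zone from natural-abundance isotopocule measurements and 15N
    tracer incubations. Implements Keeling-plot regression with a two-endmember
    atmospheric correction, a Bayesian four-pathway stable-isotope mixing model
    with a closed-system Rayleigh reduction term (jointly fitting bulk d15N, d18O
    and site preference), 15N tracer nitrification and N2O production rate and
    yield equations with detection-limit censoring, trapezoidal depth integration
    and substrate-contribution ratios, paired control-versus-acidification
    response statistics (median/IQR, percentile bootstrap, leave-one-station-out),
    headspace-equilibration gas solubility conversion, and a synthetic-data
    generator with recorded ground truth for end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
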