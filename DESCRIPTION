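Package: eddyforage
Title: Seabird Foraging Trips, Logger Fusion and Mesoscale Eddy Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for central-place foraging seabirds tracked with
    GPS and saltwater-immersion loggers. Segments tracks into colony-based
    trips, interpolates and measures them, assigns shelf/basin habitat from
    bathymetry, fuses GPS with wet/dry records to classify foraging versus
    resting at sea, estimates kernel-density core feeding areas with
    least-squares cross-validated bandwidths, derives geostrophic eddy kinetic
    energy from gridded sea-surface-height anomalies, tests association of
    foraging locations with mesoscale eddies against a randomization null, and
    computes diet frequency-of-occurrence, fledging-success and stress-hormone
    summaries. Includes a synthetic-data generator that plants known truth so
    the full chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
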