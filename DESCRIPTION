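Package: thymotrack
Title: Calcium Signaling Events and Motility Statistics from Thymocyte
    Imaging Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-photon time-lapse imaging of
    thymocytes labelled with a ratiometric calcium indicator. Reads
    per-timepoint cell-track tables exported from spot-tracking software,
    derives calcium (bound/unbound) ratio and instantaneous speed traces,
    segments calcium signaling events by hysteresis thresholding above an
    estimated nonselecting background ratio, and computes the associated
    kinetic statistics: first-complete-event durations, event-onset-aligned
    mean ratio and speed profiles, per-track pause indices, percent of
    elevated timepoints, and quiescence-bounded event frequencies. A
    synthetic-data module generates persistent-random-walk tracks with
    ground-truth calcium events and gene-by-sample expression matrices with
    planted signatures, so that every stage is testable without raw movies.
    A transcriptomic stage implements dual-criteria preselection-DP gene
    signature filtering, curated ion-channel list filtering against
    differential-expression results, and replicate-averaged row-scaled
    hierarchical clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
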