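Package: rafnet
Title: Reflexively Autocatalytic and Foodset-Generated (RAF) Networks for
    Cultural Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing catalytic reaction systems
    (CRS) and their reflexively autocatalytic, foodset-generated (RAF)
    subnetworks: foodset reachability, the maxRAF fixed-point algorithm,
    closed and transient subRAFs, irreducible RAFs, co-RAFs and union
    decomposition.  On top of the algorithmic core, the package models
    cultural lineages as provenance-tagged conceptual networks in which
    social learning and individual learning grow an individual's foodset
    while catalysed creative thought produces foodset-derived mental
    representations, and ships the Löwenmensch cross-domain-transfer case
    study (participant roster, through-line presence matrix and the
    six-step musician lineage) as packaged fixtures.  A binary polymer
    model generator produces random catalytic reaction systems with
    tunable catalysis density for phase-transition experiments and
    property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
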