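Package: specflow
Title: Country-to-Country Specimen Flow Networks from Occurrence Records
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and analyses directed, weighted country-to-country flow
    networks of natural history specimen holdings from Darwin-Core-style
    occurrence records. Provides record filtering with a full audit log,
    ISO 3166-1 alpha-3 country standardisation, institution-to-country
    resolution against a registry, temporal binning into collecting periods,
    per-slice network topology metrics (size, complexity, density,
    reciprocity, giant component, Louvain modularity), holdings inequality
    (Gini coefficients with participant-only and zero-inclusive variants),
    net importer/exporter rankings, temporal trend statistics, and a
    sensitivity-analysis suite. A synthetic occurrence-record generator with
    controlled concentration, reciprocity, and contamination makes the whole
    pipeline testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
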