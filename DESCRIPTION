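Package: pingnet
Title: Social Networks from Acoustic Telemetry Across Receiver Detection Ranges
Version: 0.1.0
Authors@R: person("pingnet", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers animal social networks from acoustic-telemetry detection
    logs using the gambit of the group: detections are grouped into
    clock-aligned time bins per receiver, aggregated into sampling periods,
    and scored with the simple ratio index. Provides data-stream (swap)
    permutation null models for tests of non-random association, Mantel
    matrix correlations and a sum-of-variances statistic for the
    consistency of individual weighted-degree ranks between networks.
    Includes an agent-based simulator of resting/travelling movement,
    tag transmissions and range-dependent detections, so the distortion
    of inferred social structure by large receiver detection ranges can
    be studied without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
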