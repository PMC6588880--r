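Package: tmtopo
Title: Transmembrane Topology Descriptors and Domain-Partition Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Descriptors and triage logic for difficult multidomain and
    polytopic membrane protein chains. Turns per-chain alignment evidence
    into an accepted domain parse or a flagged curation case with a reason
    and architecture taxonomy, and summarizes collections of outcomes into
    curation statistics. Computes transmembrane segment geometry from
    C-alpha coordinates and a membrane normal: per-segment axes, centroids,
    up/down orientation, and the chirality (handedness) of every consecutive
    segment triplet. Aligns two segment-level topology profiles by
    semi-global dynamic programming with affine internal gaps, tolerating
    inserted segments and detecting circular permutation of the segment
    order. Ships a synthetic-fixture generator (ideal helix bundles with
    prescribed centroid arrangements; partition scenarios with prescribed
    domains, fragments and masks) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
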