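Package: treecrash
Title: Severity Assessment of Vehicle Collisions with Roadside Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative severity assessment of run-off-road
    collisions between errant vehicles and roadside trees. Computes the
    standard occupant injury indices (acceleration severity index, head
    injury criterion, 3-ms chest resultant acceleration) from acceleration
    time histories, evaluates and refits published regression models that
    predict occupant injury from departure speed, tree diameter, tree
    spacing and horizontal curve radius, derives ordinal severity
    thresholds by Fisher optimal segmentation of ordered injury-index
    samples, grades crash cases on a four-level severity scale, and scores
    predicted against observed injury grades with a grade-distance
    weighted misclassification index. Includes a synthetic crash-pulse and
    simulation-grid generator for end-to-end testing without a commercial
    crash simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
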