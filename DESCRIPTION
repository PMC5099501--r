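Package: planlink
Title: Linking Provider Directories and Correlating Health-Plan Quality
    with Provider Attributes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for studying how health-insurance plan
    quality scores relate to aggregated attributes of the plans' member
    providers. Includes a synthetic-data generator emulating provider
    directories, review-site profiles, hospital rankings, procedure-charge
    records and plan quality tables with known ground truth; fuzzy record
    linkage of provider directories by weighted multi-attribute Levenshtein
    matching with blocking and threshold calibration; derivation of provider
    attributes (review ratings, referrals, awards, specialty-mapped hospital
    scores, geographic relative cost); plan-level aggregation; and a
    correlation battery (Pearson, Wilcoxon signed-rank, Mann-Whitney U) with
    state-wise and condition-specific stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
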