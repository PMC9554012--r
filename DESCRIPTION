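Package: cfpripa
Title: Consistent Fuzzy Preference Relations and Importance-Performance
    Analysis for Survey Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid multi-criteria decision-making pipeline for weighting
    and evaluating hierarchical survey instruments such as the 30-item,
    8-dimension Home Healthcare Nurse Job Satisfaction Scale (HHNJS).
    Per-respondent attribute weights are elicited from minimal chains of
    k-1 adjacent pairwise comparisons using consistent fuzzy preference
    relations (additive-transitivity completion, rescaling, and normalized
    row-sum weight derivation), aggregated across respondents with a
    leave-one-respondent-out confidence statistic, and composed into
    hierarchical global weights with ranks.  Mean Likert performance per
    criterion is paired with global-weight importance and classified into
    the four importance-performance analysis quadrants.  A synthetic
    respondent generator with controllable ground-truth weights, judgment
    noise and ordinal rating noise makes every pipeline stage testable
    without raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
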