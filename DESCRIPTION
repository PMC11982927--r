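Package: groupengage
Title: Social Engagement Analysis for Multiparty Group Conversation Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying social engagement in recorded multiparty
    group sessions, aimed at studies of group interventions for older adults
    with Alzheimer's disease and related dementias. Reads Praat pitch and
    intensity tiers, speaker diarization logs, and coded event sheets; builds
    speaker turn structure; computes per-speaker Z-normalized turn-level
    prosodic features and acoustic-prosodic entrainment (proximity) per event;
    derives speech time-budget features (speaker-group time, participant
    fraction, silence fraction); and fits the associated statistical models:
    individual and joint linear regressions of Likert engagement scores on
    behavioral, host, group-size, entrainment and time predictors, one-way
    ANOVA with eta-squared effect size and Tukey HSD after balanced
    downsampling, and inter-rater percent agreement. Includes a synthetic
    session generator with planted regression coefficients and a tunable
    entrainment strength for end-to-end validation, plus color-coded
    turn-at-talk timeline graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
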