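Package: vpcue
Title: Cue-Response Encoding Analysis for Ventral Pallidum Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular single-unit recordings from
    the ventral pallidum during Pavlovian and instrumental (discriminative
    stimulus) reward-seeking tasks. Implements peristimulus time histogram
    construction with AIC-based bin-size selection, confidence-band response
    detection with telescopic onset refinement, ROC/auROC discrimination of
    cue identity and behavioral response, trial-by-trial firing-latency
    Spearman correlations with shuffled-latency permutation nulls,
    video-tracking kinematics (velocity, port distance, movement onset),
    population contingency statistics with scaled JZS Bayes factors, and a
    synthetic-session generator emulating both task contingencies for
    testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
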