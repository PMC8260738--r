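Package: sleepreplay
Title: Decoding Reward-Biased Neural Reactivation in Sleep fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects the spontaneous reemergence during sleep of brain
    activity patterns expressed during prior waking behavior. A
    linear-chain conditional random field is trained on region-of-interest
    (ROI) fMRI time courses from a two-game block-design session, validated
    by leave-one-subject-out cross-validation, and applied to sleep-session
    data to obtain per-scan brain-state likelihoods. Likelihoods are
    aggregated by hypnogram-scored sleep stage, correlated with Welch-type
    EEG band power (notably low-delta, 1-2 Hz), and related to hippocampal
    and ventral tegmental seed-region activity and to delayed memory
    performance. A synthetic-data generator with known ground truth
    emulates the full EEG-fMRI study so every analysis runs and can be
    tested without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
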