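Package: courtsig
Title: Analysis and Modeling of Multimodal Courtship Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the two substrate- and air-borne signal
    modes that Drosophila males produce during courtship. Classifies
    pulse events into song and substrate-borne vibration by their
    inter-pulse intervals, segments pulse trains, and computes signal
    fractions, overlaps, transition probabilities and per-epoch signal
    probabilities around optogenetic stimulation. Fits a delay-embedded
    multinomial logistic model on a log-spaced raised-cosine basis to
    predict the moment-to-moment choice between song, vibration and
    silence from 19 kinematic cues, and recovers the temporal filters by
    basis back-projection. Includes a rate-based model of the underlying
    circuit (P1a, pC2l, a recurrent persistence stage, and mutually
    inhibitory descending pathways) with ablation, inhibition-removal and
    satiation experiments, plus a seeded synthetic-data generator for
    two-fly trajectories, ground-truth-driven signal labels and pulse
    event trains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
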