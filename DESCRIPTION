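Package: dyadmotion
Title: Motion Features and Interaction-Quality Statistics for
    Mother-Infant Motion-Capture Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated extraction of movement features from dyadic
    (mother-infant) optical motion-capture recordings. Marker
    trajectories are trimmed to a rated window, gap-filled by linear
    interpolation under a configurable missing-data budget, low-pass
    filtered, and converted to per-frame translational kinetic energy of
    the head, arms, and upper body using anthropometric segment-mass
    fractions. A threshold on the spike-robust mean energy segments each
    recording into movement and pause episodes, from which coarse
    (activity, overlap, silence) and fine-grained (coactive and
    alternating onset) dyadic coordination features are computed. The
    package also builds Coding Interactive Behavior (CIB) composites
    from Likert sub-scale ratings, computes Cronbach's alpha and
    ICC(2,1) reliability, and correlates features with composites using
    Spearman rank correlations. A synthetic-dyad generator with planted
    ground truth makes every stage testable without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
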