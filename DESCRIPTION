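Package: spacemot
Title: Multi-Object Tracking for Space-Animal Video with Appearance-Motion Fusion
Version: 0.1.0
Authors@R:
    person("Maintainer", "Spacemot", email = "spacemot@example.org", role = c("aut", "cre"))
Description: Joint detection and tracking of many visually near-identical small
    animals (flies, larval fish) filmed by a static camera in a microgravity
    arena, where erratic accelerations, sharp turns and frequent occlusions
    defeat appearance-only or constant-velocity trackers. Implements a
    polynomial-expansion motion decoupling stage that turns frame pairs into
    sparse polar motion features, a dual-stream multi-scale feature backbone,
    a heterogeneous graph attention network fusing appearance and motion
    queries with trajectory memory, a unified detection-tracking head with
    learned affinity association via the Hungarian algorithm, cross-modal
    confidence fusion and an embedding-based re-detection stage for identity
    recovery after occlusion. Ships CLEAR-MOT and identity metrics (MOTA,
    IDF1, Frag, MT/ML), MOTChallenge CSV readers and writers, and a seeded
    synthetic arena simulator used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
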