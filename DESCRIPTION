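Package: abstractmyo
Title: Abstract Myoelectric Prosthesis Control with Personalized Decision Boundaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An offline, testable implementation of a two-channel abstract
    myoelectric control system for prosthetic hands: bandpass/notch EMG
    preprocessing and mean-absolute-value (MAV) feature extraction, a
    two-dimensional cursor decoder with angular target regions, dwell-based
    grasp selection gated by a hand state machine, timestamped session
    logging with user-feedback labeling, and Gaussian Naive Bayes adaptation
    of the angular decision boundaries from real-life labeled decisions.
    A virtual-user simulator generates aiming behaviour, cursor trajectories
    and synthetic surface EMG so the whole pipeline can be exercised and
    validated without human or hardware data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
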