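Package: bpshoulder
Title: Musculoskeletal Shoulder Loads During Bench Press Technique Variations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for glenohumeral and
    acromioclavicular joint loading during barbell bench press technique
    variations. Generates synthetic motion-capture and instrumented-barbell
    recordings over a factorial grid of grip width, shoulder abduction angle
    and scapula pose; preprocesses marker and force streams (zero-phase
    Butterworth filtering, pulse synchronization, spline and rigid-body gap
    filling, scapula landmark reconstruction); fits a reduced parameterized
    shoulder-girdle model by inverse kinematics; resolves the muscle
    redundancy with a per-frame minimal-effort quadratic program under a
    glenohumeral stability cone constraint; decomposes joint reaction forces
    into compression and shear components; and compares cycle-normalized
    time series between technique conditions with a two-level random-effects
    statistical non-parametric mapping permutation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
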