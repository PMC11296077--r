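Package: bouncework
Title: Mechanical Work Partition and Spring-Mass-Actuator Analysis of Treadmill Running
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the full mechanical-work partition of treadmill running
    from ground reaction forces and sagittal-plane marker kinematics: external
    (centre-of-mass) work by force-plate integration, segmental internal work,
    inverse-dynamics joint work, and the soft-tissue work residual between the
    two. Fits a spring-mass-actuator model (leg stiffness and damping
    coefficient) to the projected force-leg length curve of each step and
    measures the force-length hysteresis area. Includes gait-event detection,
    zero-phase Bessel filtering, stride-level aggregation with Pearson/Fisher
    correlation analysis, and a synthetic treadmill-trial generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
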