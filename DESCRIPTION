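Package: loomtau
Title: Time-to-Contact Estimation and Collision Detection with the Corrected Modified Tau Framework
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of visual looming for time-to-contact (ttc) estimation and
    collision detection. Implements the tau and eta function family together
    with the modified tau (m-Tau) and its noise-robust corrected form (Xi),
    closed-form peak analysis for rigid-sphere constant-velocity approaches,
    first-order low-pass filtering of the optical variables, a noise-masked
    linearity analysis of peak times versus the half-size-to-speed ratio,
    a simulator of before/after ttc discrimination experiments with Gaussian
    cumulative-density psychometric fits, exhaustive grid-search parameter
    optimization with robust score measures, and nonlinear fitting of looming
    functions to firing-rate curves of collision-sensitive neurons. Includes
    seeded synthetic-data generators for optical traces, firing-rate curves
    and psychometric observer datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    nortest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
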