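Package: cprtutor
Title: Mistake Detection for CPR Training from Multimodal Sensor Data
Version: 0.1.0
Authors@R: person("cprtutor", "maintainers", email = "cprtutor@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the quality of chest compressions in
    cardiopulmonary resuscitation (CPR) training from multimodal sensor
    recordings.  Reads and writes time-synchronised multi-sensor session
    archives (skeleton tracking, electromyography and inertial streams as
    timestamped JSON frames), aligns per-compression annotation intervals,
    labels each compression against resuscitation-guideline performance
    indicators (rate, depth, release, arm locking, body-weight use), resamples
    each compression into a fixed-size feature tensor, and trains recurrent
    (long short-term memory) classifiers to detect training mistakes.  A
    kinematic simulator generates synthetic sessions with known ground truth
    and controllable mistake injection, plus a manikin emulator that derives
    per-compression measurements from the displacement trace.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
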