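Package: r2play
Title: Multi-Domain Return-to-Play Assessment Engine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Software engine for a gamified, multi-domain return-to-play
    assessment used in paediatric concussion rehabilitation. Generates
    distance-standardized trail-making protocols over a configurable tablet
    layout, defines and validates a JSON session event-log format, computes
    multi-domain cost scores (exertion, cognitive, auditory-interference,
    scramble and fatigue costs) across completion-time, error and heart-rate
    metrics, derives clinical exertion and usability summaries (age-predicted
    maximal heart rate, System Usability Scale, symptom stop rules), and
    simulates synthetic assessment sessions with controllable demand-loading
    effects so the full scoring pipeline can be exercised and parameter
    recovery demonstrated without hardware or participants.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
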