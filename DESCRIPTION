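Package: dopramp
Title: Dopamine Ramp Simulation and Photometry Analysis Under Varying
    Inter-Trial Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study when mesolimbic dopamine ramps emerge in
    cue-reward tasks. Implements a retrospective causal-learning (ANCCR)
    event simulator whose eligibility-trace time constant scales with the
    inter-reward interval; generators for Pavlovian and simulation task
    event streams with calibrated truncated-exponential inter-trial
    intervals; a two-channel fiber-photometry pipeline (isosbestic
    scaling, dF/F, onset peak and ramp-slope regression in time and in
    virtual distance); trial-level statistics relating ramp slope to
    inter-trial-interval history; and a ground-truth-known synthetic
    session generator for end-to-end validation of every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
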