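Package: vefr
Title: Visually Evoked Flow-Velocity Responses from Functional Transcranial Doppler
Version: 0.1.0
Authors@R:
    person("VEFR", "Maintainers", email = "vefr@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for functional transcranial Doppler (fTCD)
    assessments of neurovascular coupling with a block-design visual
    stimulation protocol. Extracts beat-to-beat peak systolic, end diastolic
    and mean velocities from cerebral artery velocity envelopes, segments
    ON/OFF stimulation cycles, excludes artifact-contaminated cycles, computes
    visually evoked flow-velocity responses (VEFR) per velocity index, and
    provides the cohort statistics layer (baseline tables, repeated-measures
    group comparison, habituation regression, normality screening and power
    design). Includes a synthetic-cohort generator producing pulsatile
    multi-channel recordings (velocity, arterial pressure, capnogram) at
    waveform or fast beat-level fidelity so the whole pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
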