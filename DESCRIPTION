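Package: lesionkinetics
Title: Lesion-Formation Kinetics for Local-Impedance-Guided Radiofrequency Ablation
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the time course of radiofrequency (RF)
    ablation lesion formation under local-impedance (LI) guidance. Fits
    saturating one-phase association growth curves of the LI drop and
    lesion dimensions against RF delivery time, computes the time to 90%
    decay of the peak growth rate (the boundary between the rapidly and
    slowly increasing phases of lesion formation), derives lesion volume
    from calliper axes, inverts fitted curves for threshold-crossing
    times, and runs the associated correlation, trend and group-comparison
    statistics. Includes a calibratable synthetic-experiment generator
    emulating a factorial power x contact-force x time ex vivo design, and
    a pipeline that assembles a full decay-time/threshold/correlation/
    trend report from endpoint records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
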