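Package: fusbbbo
Title: Cavitation Dosimetry, Passive Acoustic Mapping and Opening
    Quantification for Focused-Ultrasound Blood-Brain-Barrier Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microbubble-mediated focused-ultrasound
    blood-brain-barrier opening (BBBO) studies. Computes per-burst harmonic,
    ultraharmonic and broadband cavitation doses and the cumulative cavitation
    dose from passive cavitation detector recordings; reconstructs 2-D
    cavitation maps from multichannel RF by coherence-factor-weighted
    delay-and-sum beamforming; quantifies contrast-enhanced opening volumes
    from paired post-contrast T1-weighted MRI with an adaptive
    Gaussian-confidence threshold; computes amyloid-PET SUVR, asymmetry SUVR
    and Centiloid values; provides skull insertion-loss and derating
    arithmetic, targeting-error and motion metrics, and the study's
    statistical summaries. A synthetic-data module generates acoustic and
    imaging inputs with the statistical structure the analysis assumes so the
    full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    withr
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
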