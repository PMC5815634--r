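Package: ssptwin
Title: Digital Twin for Subresolution Sandwich SPECT Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and in-silico validation of subresolution sandwich
    phantoms (SSPs) for dopamine-transporter (123I-FP-CIT) SPECT. The
    toolkit fits inkjet ink-profile calibration curves and inverts them
    for target compartment activity ratios, renders per-sheet greyscale
    print templates from brain and striatal label volumes, assembles a
    voxelised digital phantom (activity plus attenuation), simulates
    dual-head parallel-beam SPECT acquisition with depth-dependent
    collimator blur and Poisson counting, reconstructs with OSEM and a
    Butterworth post-filter at clinical settings, and quantifies striatal
    binding ratios, striatal shape (anterior-posterior over
    medial-lateral aspect ratios) and Dice overlap against the template.
    A fixtures module generates a stylised head and synthetic calibration
    data so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
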