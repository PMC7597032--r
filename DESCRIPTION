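Package: footload
Title: Foot Bone Architecture and Regional Plantar Load Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking static weight-bearing three-dimensional
    foot skeletal architecture with dynamic regional plantar loading. Reads
    per-bone surface meshes (STL), builds a ground-referenced foot anatomical
    frame and PCA-based bone-embedded frames, and derives 84 named skeletal
    variables (absolute/relative inclination angles in 3D and in the lateral,
    frontal and transverse planes, plus absolute and relative minimum bone
    heights). Processes dynamic plantar-pressure recordings into regional peak
    pressure, pressure-time integrals and contact-time-normalised integrals
    over marker-based anatomically masked forefoot regions, plus contact time
    and arch index. Computes a composite neuropathy score, assigns patient
    groups, and runs an exhaustive Pearson correlation screen with
    significance filtering and strength classification. Includes a synthetic
    generator for bone meshes, pressure trials and clinical cohorts with
    planted ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
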