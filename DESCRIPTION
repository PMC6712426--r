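Package: perispect
Title: Serial MR Spectroscopy Quantification and Lesion Volumetry for
    Perihematomal Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for serial proton MR
    spectroscopy studies of intracerebral hemorrhage. Provides a forward
    simulator for chemical shift imaging (CSI) voxel spectra with known
    ground-truth metabolite concentrations, FLAIR-like lesion phantoms with
    known volumes, and longitudinal cohorts with animal-level random
    effects; automated zero/first-order phase correction and windowed peak
    integration; water-referenced absolute quantification of NAA, creatine
    and choline with T1/T2 relaxation correction; seed-growing segmentation
    of hematoma, perihematomal edema and intracranial volume with
    longitudinal volume summaries; and linear mixed-model inference over
    region-by-time contrasts with Satterthwaite degrees of freedom.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    RNifti,
    lme4,
    lmerTest,
    pracma,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
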