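Package: lesionmap
Title: Voxel-Based Lesion-Symptom Mapping with Survival Validation
Version: 0.1.0
Authors@R: person("lesionmap", "maintainers", email = "maintainers@lesionmap.invalid", role = c("aut", "cre"))
Description: Mass-univariate voxel-based lesion-symptom mapping (VLSM) for
    cohorts of binary lesion masks on a shared reference grid. Fits a
    voxelwise general linear model relating lesion presence to a clinical
    outcome (performance score or overall survival) with covariate control,
    assesses significance by permutation testing with Benjamini-Hochberg
    false-discovery-rate correction, extracts significant regions of
    interest, quantifies their overlap with white-matter tract atlases, and
    validates region involvement as a risk factor via Kaplan-Meier/log-rank
    analysis, Cox hazard ratios, and fixed-horizon survival ROC. Includes a
    fully synthetic lesion-cohort generator with a ground-truth effect
    region so the whole pipeline is testable without patient data, plus
    minimal NIfTI-1 input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
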