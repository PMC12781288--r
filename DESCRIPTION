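Package: ANMtools
Title: Activation Network Mapping for Coordinate-Based fMRI Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements activation network mapping (ANM), a coordinate-based
    meta-analytic method that projects per-study activation peak coordinates
    onto brain networks using seed-based resting-state functional connectivity
    in a normative connectome. Builds per-study coactivation seeds (unions of
    fixed-radius spheres around reported peaks), computes participant-level
    seed-to-voxel Fisher z connectivity maps, aggregates them into group-level
    overlap maps (voxels connected to more than a fixed fraction of seeds) and
    one-sample t maps, contrasts groups, quantifies map similarity, and emits
    atlas-labelled peak tables. Includes a synthetic normative-connectome and
    foci generator with planted ground-truth networks for parameter-recovery
    validation, NIfTI input/output, and Talairach to MNI coordinate conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'ANMtools-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'volumes.R'
    'foci.R'
    'seeds.R'
    'network-maps.R'
    'reporting.R'
    'synthetic.R'
    'pipeline.R'
    'utils.R'
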