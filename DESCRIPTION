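Package: blockfmri
Title: Block-Design fMRI Simulation, Functional ROIs and Searchlight RSA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative block-design task fMRI studies of visual
    category perception (faces, bodies, inanimate objects) in dogs and humans.
    Provides a synthetic-data generator with known ground truth (stimuli, block
    designs, BOLD runs, motion traces), stimulus low-level-property measures
    (hue, saturation, contrast, spatial extent), voxel-wise GLMs with
    species-specific haemodynamic response functions and framewise-displacement
    motion scrubbing, split-half functional-ROI definition with top-percent
    voxel selection, whole-brain searchlight representational similarity
    analysis, and permutation-based cluster-level inference with FDR-corrected
    planned comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    png,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
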