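Package: rsnselect
Title: Automatic Selection of Resting-State Network Components from Spatial ICA
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies resting-state-network components in a spatial
    independent component analysis (ICA) decomposition of resting-state
    fMRI data using a four-step filter: rejection of components whose
    spatial maps are symmetric (noise-like) by Pearson's median skewness
    coefficient, one-dimensional k-means voxel filtering with
    silhouette-based selection of the number of clusters, masking of
    voxels with high white-matter or cerebrospinal-fluid probability,
    and periodogram band-power rejection of components without dominant
    low-frequency (0.01-0.1 Hz) fluctuations. Reads and writes
    MELODIC-style decompositions (4-D NIfTI spatial maps plus a plain-text
    mixing matrix), provides evaluation metrics (confusion counts,
    accuracy, precision, cross-session component matching), a synthetic
    decomposition generator for testing without scanner data, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
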