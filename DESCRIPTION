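Package: dgnet
Title: Population Analysis of Dentate Gyrus Network Events in Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and statistical analysis of synchronous network events in
    two-photon calcium imaging of hippocampal dentate granule cells. Provides
    shuffle-calibrated synchronous event detection from binarized event rasters,
    cosine-similarity orthogonality tests, permutation-thresholded agglomerative
    clustering of correlated sub-ensembles, spatial tuning vector and speed
    tuning tests for place and speed cells, bulk input-pathway signal
    conditioning and deconvolution with cross-correlation and Granger tests,
    pupil-state statistics, PCA-based subspace similarity between locomotion and
    immobility activity (projected variance ratio, S_PCA, EROS), and a synthetic
    session generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    signal,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
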