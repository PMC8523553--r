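Package: mvcsi
Title: Multivoxel Correlation Structure Similarity Analysis for fMRI ROI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the persistence of local multivoxel activity
    patterns across fMRI runs via multivoxel correlation structure (MVCS)
    analysis. Provides ROI time-series preprocessing (detrending, discrete-
    cosine high-pass filtering, framewise-displacement scrubbing, down-sampling
    across repetition times, gray-matter voxel selection, motion and tissue-
    component nuisance regression, volume matching), MVCS matrix and
    similarity-index computation for run pairings (early vs late task practice,
    pre vs post rest, task vs post rest), serial reaction time task performance
    measures, repeated-measures linear mixed models with unstructured and
    Kronecker-product covariance structures and Satterthwaite degrees of
    freedom, Benjamini-Hochberg false-discovery-rate correction across regions,
    and a synthetic-study generator with known ground truth for validation and
    power/calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), nlme, RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
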