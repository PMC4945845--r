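Package: lungqct
Title: Quantitative Chest CT Analysis of Pulmonary Congestion and Airway
    Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative analysis of thoracic CT volumes for studies of
    pulmonary congestion and airway structure in heart failure.  Computes
    attenuation-histogram indices of extravascular lung water (mean HU,
    skewness, kurtosis, full width at half maximum, percentage of voxels
    above -500 HU), partitions each voxel into air and tissue volumes,
    segments the airway tree by leak-controlled region growing, measures
    per-generation luminal area and wall thickness with half-maximum edge
    detection, and runs the cohort statistics (Welch and paired t-tests,
    Bonferroni correction across generations, Pearson correlation screens)
    that compare patient groups and pre/post bronchodilator states.  A
    ground-truthed digital thorax phantom generator provides synthetic
    volumes and cohorts so every stage is verifiable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
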