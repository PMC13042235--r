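Package: zmapendo
Title: Individualized Z-Map Imaging Endophenotypes for Juvenile Myoclonic Epilepsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for individualized Z-mapped imaging
    endophenotypes of cortical and subcortical brain morphometry in
    juvenile myoclonic epilepsy. Provides normative covariate correction of
    regional morphometry (generalized additive models with an age smooth and
    linear sex and brain-volume terms fitted on healthy controls),
    leave-one-out z-scoring of controls and z-scoring of patients against the
    full control distribution, lobar composite aggregation, two-sample
    Kolmogorov-Smirnov distribution comparison with false-discovery-rate
    correction, stability-selected K-means endophenotyping (elbow, gap
    statistic and bootstrapped Jaccard coefficients), endophenotype-wise
    clinical and cognitive comparisons, and a synthetic cohort generator with
    planted endophenotypes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    e1071,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
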