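Package: langmorph
Title: Voxel-Based Morphometry and Behavioral PLS for Language-Related
    Individual Differences in Brain Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for studying individual differences in
    structural brain volumes in relation to language: voxel-wise general
    linear models on modulated gray- and white-matter maps with
    permutation-based cluster-level FDR inference, a conjunction-overlap
    commonality statistic with a smoothness-matched Monte-Carlo null,
    behavioral Partial Least Squares (singular value decomposition of
    brain-behavior correlation matrices) with permutation and bootstrap
    inference, sphere region-of-interest replication tests, and effect
    sizes computed from printed summary statistics. Includes a synthetic
    cohort generator producing NIfTI volumes and behavioral tables with
    the statistical structure the analyses assume, so the whole pipeline
    is testable without access to restricted MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
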