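Package: dvmix
Title: Model-Based Clustering for Differential Variability in Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic probes (e.g., microRNAs) whose expression
    variance differs between two groups of subjects (cases versus controls).
    Probes are clustered into over-variable (OV), equal-variance (EV), and
    under-variable (UV) classes with a three-component mixture of
    multivariate normal distributions with exchangeable (compound-symmetry)
    within-group covariance, fitted by a constrained EM algorithm.
    Includes probe-wise equal-variance baselines (F test, Levene,
    Brown-Forsythe, trimmed-mean Levene) with false-discovery-rate
    adjustment, simulation generators with ground truth, partition
    agreement metrics (pair-counting Jaccard index, false positive and
    false negative rates), Box-Cox preprocessing, and a
    discovery-validation workflow with bootstrap validation rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
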