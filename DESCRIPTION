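Package: twinewas
Title: Paired and Unpaired Epigenome-Wide Association Scans for
    Monozygotic Twin Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for epigenome-wide association studies (EWAS) of
    quantitative phenotypes in monozygotic twin cohorts profiled on
    Illumina 450K-style methylation arrays. Implements probe-level
    quality filtering and the beta to M-value transform, construction of
    a six-test cognitive composite score with prorating and a 10-year
    change score, imputation of missing blood leukocyte counts by
    partial least squares regression, the within-pair difference
    (paired) association scan with discordance-stratified subsetting,
    the individual-level (unpaired) scan with a twin-pair random
    intercept fitted by profiled REML, threshold reporting with probe
    annotation and cross-analysis overlap, hypergeometric gene-set
    over-representation analysis, and a synthetic monozygotic-twin
    cohort generator with ground truth so every stage is testable
    without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    mixOmics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
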