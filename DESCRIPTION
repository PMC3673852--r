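Package: sepchan
Title: Separate-Channel Analysis of Two-Colour Microarrays with a Common
    Intra-Spot Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Differential-expression analysis of two-channel (two-colour)
    microarrays that recovers the between-spot information discarded by the
    traditional log-ratio analysis.  Channel log-intensities are
    reparameterized into within-spot log-ratios (M-values) and spot mean
    log-intensities (A-values), a per-gene two-stratum REML fit estimates
    the M- and A-variances with leverage-based fractional degrees of
    freedom, and a bias-corrected trimmed mean of the per-gene variance
    ratios pools them into a single intra-spot correlation.  Treating that
    correlation as known turns the heteroscedastic model into ordinary
    least squares on rescaled data, feeding an empirical Bayes moderated
    t-statistic pipeline with exact null distributions.  Includes
    closed-form design-efficiency calculators (common-reference,
    unconnected and paired layouts) and a mixed-model simulator for
    two-channel experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, limma
Suggests: testthat (>= 3.0.0), statmod, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
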