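Package: trimix
Title: Multiple-Testing-Adjusted Disease Mapping with Tri-Level Bayesian
    Mixture Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens small-area disease maps for areas whose relative risk
    diverges from a reference while controlling for multiple testing.
    Implements exact Poisson per-area tests with Bonferroni, (adaptive)
    Benjamini-Hochberg and Storey q-value corrections, funnel-plot control
    limits, and a tri-level hierarchical Bayesian mixture model (point-mass
    null versus Poisson-Gamma or Besag-York-Mollie alternative, with a
    Beta-Bernoulli null-membership layer) fitted by Markov chain Monte
    Carlo, yielding per-area posterior classification probabilities.
    Includes a seeded generator of synthetic areal maps with known truth
    and procedure-comparison utilities (cross-tabulation, proportion of
    specific agreement, quantile-quantile exports).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), coda, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
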