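Package: tastecircuit
Title: Structural and Effective Connectivity Analysis of the Taste-Reward Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing structural and effective connectivity in the
    taste-reward brain circuit. Computes normalized tract connection strength
    from probabilistic-tractography streamline counts, recovers directed
    effective-connectivity graphs from multi-subject ROI time series by greedy
    equivalence search with a BIC score, a multi-sample score extension, and a
    fixed-structure non-Gaussian orientation post-processor, and provides the
    surrounding group statistics (summary-statistics ANOVA, covariate-adjusted
    group models, post-hoc tests, Kruskal-Wallis, brain-behavior regression,
    Benjamini-Hochberg FDR). A synthetic-data module generates every pipeline
    input with known ground truth: linear non-Gaussian structural-equation time
    series over the circuit regions, streamline-count matrices with group
    effects, the probabilistic conditioned-taste task schedule, and behavioral
    tables matched to published summary moments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
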