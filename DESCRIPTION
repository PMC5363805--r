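Package: gomclust
Title: Grade-of-Membership Clustering for RNA-Seq Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits grade-of-membership (topic) models to samples-by-genes read
    count matrices by EM-based maximum a posteriori estimation with Dirichlet
    priors and multi-restart selection. Provides Poisson Kullback-Leibler
    driving-gene scores for cluster annotation, Structure-plot visualization
    of membership proportions, binomial thinning to emulate reduced sequencing
    depth, a pairwise two-group separation benchmark against hierarchical
    clustering, and a generative simulator with known ground truth spanning
    bulk and single-cell library-size regimes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
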