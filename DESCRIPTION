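Package: odflow
Title: Origin-Destination Networks and Long-Range Mobility from Trip Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse point-to-point trip records (for example taxi
    pick-up/drop-off coordinates) as a spatially embedded directed weighted
    network. Trips are binned on a square grid, high-demand zones are
    selected, and an origin-destination (OD) count matrix is built together
    with its in/out degrees and displacement statistics. The package fits
    heavy-tailed degree distributions (power law, power law with exponential
    cutoff, exponential, stretched exponential, log-normal) by continuous
    maximum likelihood with Kolmogorov-Smirnov and Vuong likelihood-ratio
    model selection, estimates a piecewise distance kernel (constant within
    a radius R, truncated-Levy decay beyond) from transition probabilities,
    computes the spectral "OD rank" (stationary distribution of the
    row-stochastic transition matrix) with its mean-field PageRank
    approximation, and provides a Monte Carlo mobility simulator driven by
    the fitted kernel. A synthetic trip generator reproduces the statistical
    structure the analysis assumes so every stage can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    geosphere,
    pracma,
    jsonlite,
    yaml,
    methods,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
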