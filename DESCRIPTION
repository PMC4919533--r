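Package: convzone
Title: Convergence-Zone Analysis of Conjunctive Coding and Network Hubness
Version: 0.1.0
Authors@R:
    person("convzone", "developers", email = "convzone@example.org",
           role = c("aut", "cre"))
Description: Tools to localise mnemonic convergence zones in volumetric
    imaging data by combining two complementary voxel-wise metrics:
    conjunctiveness, estimated with searchlight representational similarity
    analysis under a balanced associative contrast with perception-penalty
    exclusions, and hubness, estimated as the participation coefficient of
    beta-series connectivity graphs partitioned into subnetworks with the
    Louvain method. Group inference uses sign-flip permutation tests, and
    the spatial coincidence of the two thresholded maps is tested against
    an atlas-region resampling null using Dice and relative-overlap
    statistics. Includes a synthetic multi-subject beta-image generator
    with planted conjunctive, perceptual and hub effects, minimal NIfTI-1
    input/output, and a command-line interface for each pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
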