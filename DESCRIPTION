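Package: coaltest
Title: Coalescent Bootstrap Likelihood Ratio Tests for Competing Species Trees
Version: 0.1.0
Authors@R:
    person("Georg", "Hartmann", email = "g.hartmann@example.org",
           role = c("aut", "cre"))
Description: Compares candidate species trees against a set of rooted gene
    trees under the multispecies coalescent. Implements the rooted-triple
    pseudo-likelihood of a species tree with branch lengths in coalescent
    units, a parametric-bootstrap likelihood ratio test (cbLRT) between two
    candidate topologies, and a sequential test over a ranked list of
    candidates. Ships the supporting toolkit used around such tests:
    Robinson-Foulds and normalized Robinson-Foulds distances with pruning to
    shared taxa, bootstrap-quantile standardization of tree distances,
    alignment summaries (parsimony-informative sites, GC content, base
    frequencies) with a chi-squared comparison between alignment stages, a
    5X long-terminal-branch sequence filter against a reference tree,
    standardized divergence-time comparison between posterior estimates, and
    seedable simulators (censored multispecies coalescent gene trees,
    Jukes-Cantor alignments) so every operation is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
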