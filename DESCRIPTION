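Package: habtrans
Title: Habitat Transition Rates, Timings and Ancestral Habitats on
    Environmental-Sequencing Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring the evolution of marine/non-marine habitat
    preference across large molecular phylogenies. Implements the two-state
    continuous-time Markov (Mk2) model of habitat evolution with clade-specific
    rate regimes, Felsenstein pruning likelihoods, reversible-jump MCMC under
    an exponential hyperprior, stepping-stone marginal likelihoods and
    Bayes-factor model comparison, marginal and exact joint maximum-likelihood
    ancestral state reconstruction, persistence-filtered transition-event
    counting with relative timings on mean-path-length chronograms, unweighted
    UniFrac community comparisons with permutation tests, sequence-similarity
    network assortativity, and a synthetic-data generator that produces
    birth-death trees, simulated habitat histories with recorded ground truth
    and study-like data bundles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
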