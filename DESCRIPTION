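Package: aarecode
Title: Amino Acid Recoding and Model Adequacy in Phylogenomic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate amino acid recoding strategies (Dayhoff-6 and
    randomised six-state schemes) for phylogenomic inference. Simulates
    site-compositionally heterogeneous alignments under profile-mixture
    substitution models with Gamma rate variation on Farris-zone and
    Felsenstein-zone trees, applies recoding schemes, infers topology support
    by maximum likelihood and Metropolis-Hastings sampling over candidate
    topologies, quantifies model adequacy with posterior predictive Z-scores
    (diversity and compositional statistics), and measures saturation and
    parsimony-based information loss. Includes an experiment pipeline relating
    changes in model adequacy to changes in phylogenetic accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
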