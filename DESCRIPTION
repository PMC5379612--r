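Package: DefenseFlux
Title: Phylogenetic Birth-and-Death Analysis of Gene Gain and Loss in
    Microbial Defense Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction of gene gain and loss dynamics of prokaryotic
    defense systems from gene-family phyletic profiles on a rooted species
    tree. Implements a linear birth-death-immigration model of gene family
    size (gain rate kappa, per-copy duplication rate lambda, per-copy loss
    rate mu), maximum-likelihood fitting with discrete gamma rate
    categories, posterior decoding of gain, loss, expansion and reduction
    events on every tree edge, normalization of event counts into
    per-family per-genome rates, defense-versus-all relative-rate tables
    with flux classification and principal component summaries, and
    randomization tests for chromosomal co-localization of defense genes
    and of inferred events. Includes an exact stochastic simulator of
    gene-family evolution and chromosome organisation for validation with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
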