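Package: refates
Title: Recurrent Sequence Evolution Between Independently Duplicated Paralogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects recurrent sequence evolution between paralog pairs that
    arose by independent gene duplications in different species.  The unit of
    analysis is the quartet: two aligned paralog pairs from two species.  Site
    patterns supporting the three unrooted quartet topologies (Q, R, S) are
    counted, the duplication score D = 1 - w(Q) is obtained from expected
    likelihood weights under an LG+Gamma model, and the fate similarity
    F = |nR - nS| / (nQ + nR + nS) with its standard score Z(F) quantifies the
    secondary, fate-like signal.  Quartet scores are integrated over a family
    through a species-level duplication network (weighted cluster editing) and
    a gene-level fate network (Markov clustering), and alignment bootstrapping
    yields robust fate clusters from which the family-level pervasiveness P
    and magnitude mean-Z(F) are computed.  Downstream tools classify quartets
    (single versus independent duplication, whole-genome duplication
    annotation), measure asymmetric divergence, relate fates to predicted
    subcellular localization, and map the recurrent signal back onto alignment
    columns.  A gene-family simulator with known duplication events, fates and
    diagnostic columns provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    yaml
Config/testthat/edition: 3
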