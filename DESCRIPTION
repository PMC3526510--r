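Package: lignoCAZy
Title: CAZyme Annotation, Functional Diversification and Lignocellulose
    Induction Analysis for Fungal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for re-annotating the carbohydrate-active enzyme
    (CAZyme) complement of a fungal genome and for analysing its
    transcriptional induction on lignocellulosic substrates. Homology
    search hit tables against a family-labelled CAZy reference are
    filtered and turned into membership calls, protein homology clusters
    receive a CAZy family by majority vote, and species-tagged gene trees
    are scanned for duplications that predate a focal clade's ancestor to
    partition paralogues into functional subgroups. Expression matrices
    from induction experiments are contrasted against time-matched
    uninduced controls with an empirical-Bayes moderated t-statistic and
    dual significance/fold-change thresholds, yielding induction calls,
    core induced gene sets, per-family induction matrices and
    co-expression branches. Seeded synthetic-data generators with known
    ground truth support testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    stringi,
    tools,
    utils
Suggests:
    limma,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
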