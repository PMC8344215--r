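Package: MitoKaryo
Title: Fragmented Mitochondrial Karyotype Evolution in Parasitic Lice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing fragmented mitochondrial (mt) genomes that
    consist of multiple circular minichromosomes, as found in the sucking
    lice of mammals. Provides a plain-text karyotype format with parser,
    writer and validator; backbone projection and pairwise karyotype
    comparison; parsimony inference of ancestral karyotypes on a fixed
    rooted phylogeny with least-changes tie-breaking; detection and
    classification of tRNA gene translocation events relative to the
    control region (NCR) boundaries; insertion-site census statistics with
    pooled two-sample t tests; and a forward simulator of tRNA
    translocation on a tree with a controllable bias towards NCR-adjacent
    destinations, for detector round-trip and statistical calibration
    experiments. Ships karyotype fixtures for sixteen louse taxa and a
    one-shot reproduction pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
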