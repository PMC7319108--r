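Package: plastomark
Title: Comparative Plastomics Marker Screening and Chloroplast Phylogeography
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens whole-plastome alignments for mutational hotspot regions
    and polymorphic chloroplast microsatellites (cpSSRs), and carries the
    selected markers through a chloroplast phylogeography workflow: haplotype
    collapsing with indel recoding, Nei diversity statistics, Pons-Petit
    Hs/Ht/Gst/Nst with a permutation test for phylogeographic structure,
    hierarchical AMOVA with Phi-statistics, median-joining haplotype networks,
    and model-based clustering of haploid multilocus cpSSR genotypes with
    Evanno delta-K model choice. A synthetic plastome-population generator
    with quadripartite genome structure, AT-biased hotspots and structured
    demes makes every stage testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
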