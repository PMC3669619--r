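Package: phylotastic
Title: Custom Phylogenies from Megatrees by Name Resolution, Pruning,
    Grafting and Age Scaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Turns a list of taxon names into a custom, branch-length-bearing
    phylogeny derived from large pre-computed source trees ("megatrees").
    Provides scored taxonomic name resolution over local taxonomy tables
    (exact, synonym, cross-field and fuzzy matching), best-coverage source
    tree selection, fast megatree pruning via a denormalized taxon-to-root
    path index, Phylomatic-style taxonomic grafting from slash-delimited
    taxonomic paths, bladj-style even-spacing node age interpolation, and
    MRCA-age queries over a local store of time-calibrated trees with
    precomputed patristic matrices.  A controller chains the stages into a
    reproducible pipeline with JSON provenance, and a thin command-line
    interface exposes each stage standalone.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    tibble,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
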