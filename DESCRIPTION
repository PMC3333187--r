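Package: tetrabin
Title: Composition-Based Taxonomic Binning of Metagenomic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free taxonomic classification of metagenomic reads from
    tetranucleotide composition. Reference genomes are split into 1 kb fragments
    whose 4-mer frequency vectors are clustered with k-means; each read is matched
    by Manhattan distance against the nearest cluster, the distance to the closest
    fragment selects the most specific taxonomic rank the assignment may use, taxon
    proportions in the closest-fragment subset are normalized against database
    representation bias, and the read is assigned at the most specific rank where
    the subset converges on one taxon. Includes a synthetic genome/taxonomy/read
    simulator and a leave-clade-out evaluation harness, so the whole pipeline runs
    and is tested offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
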