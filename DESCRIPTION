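Package: polyclust
Title: Density-Based Genotype Calling for Polyploid SNP Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-free genotype calling for two-channel SNP-array intensity
    data from polyploid species, where duplicated gene copies compress and
    multiply genotype clusters. Implements density-based clustering (DBSCAN
    and OPTICS reachability analysis with forced-k cluster extraction), a
    three-step calling protocol with cluster-number, call-rate and minor
    allele frequency filtering, confidence-limited sample assignment,
    low-intensity null-allele (presence-absence) detection, and resolution of
    multi-cluster assays into biallelic loci via segregation in bi-parental
    mapping populations. Ships a dosage-driven intensity simulator emulating
    polyploid cluster geometry (cluster compression from homoeologous copies,
    secondary probe-site variants, deletion-derived null clusters) plus a
    small population-genetics layer (minor allele frequency, expected
    heterozygosity, Weir-Cockerham F_ST, linkage-disequilibrium r squared).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    yaml,
    vcfR,
    jsonlite
Config/testthat/edition: 3
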