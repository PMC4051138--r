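Package: aliensnp
Title: Alien Chromosome-Specific SNP Discovery and Introgression Mapping
    in Polyploid Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discovers single-nucleotide markers that distinguish an alien
    (wild-relative) chromosome arm from all three homoeologous copies of a
    hexaploid wheat chromosome group. Reads from a flow-sorted alien arm are
    quality-trimmed, mapped independently against the A-, B- and D-genome
    homoeologous assemblies under a strict mismatch budget with a single
    unique best placement, and variants are called and filtered by depth and
    phred-scaled quality. Sites where the three wheat homoeologues share one
    allele and the alien arm carries another, embedded in 100-bp flanks that
    are identical across the trio and free of nearby variation, are promoted
    to assay-ready KASP-style markers. Genotype tables of such markers across
    addition, substitution and translocation line panels are classified into
    whole-arm and partial introgressions with BED-style segment calls. A
    synthetic-data module simulates diverged homoeologous trios, alien arms
    with planted marker sites, and error-bearing quality-scored reads so the
    whole pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
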