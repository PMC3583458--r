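Package: homeosort
Title: Subgenome Assignment of Sequencing Reads from Allopolyploids
Version: 0.1.0
Authors@R: person("Repository", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds an index of homoeologous single-nucleotide differences
    (homoeo-SNPs) between the two subgenomes of an allopolyploid from
    pileups of its diploid relatives against a single reference, and uses
    that index to assign aligned reads to their genome of origin
    (categories A, D, chimeric X, or unknown N). Includes strand-aware,
    conversion-tolerant handling of bisulfite-treated reads with
    per-genome CG/CHG/CHH methylation reporting, index-level genomic
    statistics (SNP density, per-gene counts, theoretical
    categorizability), a seeded simulator of diverged genome pairs with
    truth labels, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
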