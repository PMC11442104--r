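Package: armscaps
Title: ARMS and CAPS Marker Design from Resequencing Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects cultivar-specific SNP positions from whole-genome
    resequencing alignments of two cultivars against a shared reference and
    automatically designs allele-specific PCR (tri- and tetra-primer ARMS)
    and restriction-site (CAPS) genotyping markers. Genotype filtering uses
    exact binomial confidence intervals of the SNP-index as a function of
    coverage depth, ploidy and variant-allele dosage, supporting homozygous,
    heterozygous-by-dosage (simplex/duplex/triplex) and progeny-validated
    selection. Includes in-silico PCR and restriction-digestion oracles, an
    annotated HTML report highlighting polymorphic or low-coverage amplicon
    positions, a command-line interface, and a synthetic read-alignment
    generator for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    data.table,
    methods,
    yaml,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
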