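Package: vircontrast
Title: Genome Contrast of Selfing Lines Against a Reference: Variant
    Effects, Homozygosity Mapping and Candidate-Gene Filtering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of whole-genome resequencing variant
    calls for two diploid selfing lines contrasted against a shared
    reference genome. Classifies every variant by genomic region and
    coding consequence (synonymous, nonsynonymous, stop gain/loss,
    frameshift, in-frame indel, structural-variant CDS overlap),
    contrasts zygosity and allele content between the two lines per
    locus, maps runs of homozygous variation with a sliding-window
    heterozygosity scan, summarises transition/transversion ratios,
    indel length spectra and region-wise variant densities, tests
    Pfam-domain nonsynonymous/synonymous SNP enrichment with a
    chi-squared statistic, and filters candidate genes carrying
    protein-altering variants. Includes a synthetic diploid variant
    simulator with a full truth table for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
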