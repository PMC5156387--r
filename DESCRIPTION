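Package: megadesign
Title: Custom Content Design and Evaluation for Multi-Ethnic Genotyping Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing custom content on multi-ethnic genotyping
    arrays and evaluating the resulting scaffold. Reads phased haplotype
    panels from VCF, ranks GWAS-catalog associations to pick priority loci,
    selects cross-population tag SNPs by greedy maximum coverage over a
    fixed scaffold, extracts fine-mapping LD proxies around index variants,
    consolidates multi-annotator consequence calls into a design manifest,
    and measures leave-one-out imputation accuracy stratified by population
    and minor-allele-frequency bin using a haploid Li-Stephens hidden Markov
    model. A multi-population haplotype simulator (Balding-Nichols allele
    frequency divergence plus a founder-mosaic recombination model) makes
    every stage testable without external reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
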