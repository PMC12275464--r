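Package: mitosieve
Title: Methylation-Based Discrimination of Mitochondrial and NuMT Nanopore Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Separates true mitochondrial DNA (mtDNA) reads from nuclear
    mitochondrial segment (NuMT) reads in Oxford Nanopore modified-base BAM
    files. Human mtDNA carries essentially no CpG methylation while NuMTs are
    methylated like the surrounding nuclear genome, so per-read CpG methylation
    quantified from the SAM MM/ML modified-base tags discriminates the two read
    origins. The package provides a lossless MM/ML tag codec (including
    stripping of 5hmC calls), per-read CpG methylation screening, threshold
    partitioning of BAM files into unmethylated and methylated outputs,
    strand-composition (GC/AT skew) and overlap validation statistics, and a
    synthetic modBAM generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
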