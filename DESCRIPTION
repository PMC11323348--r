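Package: sketchcov
Title: Alignment-Free Multi-Sample Contig Coverage from K-mer Sketches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-contig, per-sample read depth for metagenomic
    binning without read alignment. Reads are sketched once per sample into
    FracMinHash-subsampled canonical k-mer count tables; contig k-mers are
    then queried against every sample's table to decide presence via
    containment average nucleotide identity (ANI) and to estimate fold
    coverage with a three-regime k-mer multiplicity estimator plus a trimmed
    coverage variance. Depth matrices are written in the MetaBAT2
    (jgi_summarize_bam_contig_depths) layout or as MaxBin2-style abundance
    files. Includes a seeded synthetic-community simulator (genomes, strain
    variants at controlled identity, Poisson-sampled reads) for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
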