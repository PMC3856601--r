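Package: contigwarehouse
Title: A Searchable Warehouse for Assembled Transcriptome Contigs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns assembled transcriptome contigs plus annotation evidence
    into a structured, searchable, set-oriented resource. Reads FASTA, FASTQ,
    consed-style ACE assemblies, NCBI BLAST XML reports and InterProScan GFF3;
    stores contigs with per-base coverage and quality tracks inside a
    study/sample/assembly hierarchy; computes per-contig properties (length,
    GC content, mean coverage, mean quality); retains the top similarity hits
    per contig and all protein-domain matches; supports boolean full-text
    annotation search with stopword removal and Porter stemming, property
    range filtering, and contig-set algebra; and assembles renderer-agnostic
    report and plot data (scatter and histogram series) with ggplot2 display
    methods. A synthetic-fixture generator produces toy assemblies and
    annotation evidence with machine-readable ground truth. A command-line
    interface ties the ingestion, annotation, search and reporting workflows
    together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
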