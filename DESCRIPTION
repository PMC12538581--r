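Package: iprdesign
Title: Intergenic Promoter Region Scoring and Payload Insertion-Site
    Design for Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Selects payload insertion sites in annotated phage genomes.
    Extracts extended intergenic regions from a GenBank record (merging
    split, intron-containing gene loci into contiguous spans), ingests
    sigma70 promoter predictions from an external predictor table or from
    a built-in consensus position-weight-matrix scanner, applies an
    exponential score weighting, aggregates predictions into ranked
    Intergenic Promoter Regions (IPRs), selects insertion loci immediately
    downstream of the first same-orientation gene after each IPR, and
    designs homologous-recombination donor constructs with 200-400 bp
    homology arms and an RBS-preserving base-duplication rule for short
    downstream gaps. Includes a seeded synthetic-genome generator with
    planted promoter clusters for end-to-end testing, and writers for
    BED6, GFF3, FASTA, GenBank and TSV reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
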