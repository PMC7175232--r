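Package: paralogdiv
Title: Divergence and Diversity Analysis of Tandem Gene Duplicates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics and population-genetics toolkit for pairs of
    gene paralogs, built around the tandemly duplicated beta-COP coatomer genes
    of Arabidopsis thaliana. Classifies paralog pairs as tandem duplications by
    intergenic distance, threads protein alignments back onto coding sequences,
    estimates divergence as the transversion proportion at fourfold-degenerate
    sites (4DTv, with Kimura-type multiple-hit correction) and as Nei-Gojobori
    (1986) Ka/Ks, computes per-gene nucleotide diversity (pi) from SnpEff
    annotated variant panels with impact-based filtering in the VariScan style,
    and implements the electrolyte-leakage, cotyledon-greening and
    comparative-Ct assay formulas. Ships simulators for codon-pair evolution,
    neutral SNP panels and planted paralog genomes so that every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
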