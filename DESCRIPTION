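Package: haplomethyl
Title: mtDNA Haplotype Effects on DNA Methylation, Replication and Divergence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studies linking mitochondrial DNA (mtDNA)
    haplotypes to nuclear DNA-methylation and expression phenotypes in
    otherwise isogenic cell lines. Implements differential-methylation calling
    from two-channel MeDIP CpG-island microarrays via a fourfold log-ratio plus
    melting-temperature-binned Z-score filter cascade with line-exclusive
    hyper/hypomethylated gene classification; absolute qPCR quantification
    (standard curves, mtDNA copies per cell), delta-delta-Ct relative
    expression, percent-input MeDIP/ChIP enrichment and Fluidigm delta-Ct
    expression matrices with euclidean clustering; the composite mtDNA
    replicative-efficiency statistic (copy number against the 5mC/5hmC ratio at
    the PolgA exon-2 CpG island); plate-reader enzyme-assay arithmetic
    (alpha-ketoglutarate standard-curve inversion, MDH2 specific activity from
    kinetic absorbance rates); and calibrated mtDNA divergence-time
    phylogenetics (pairwise GTR+Gamma maximum-likelihood distances,
    neighbor-joining with bootstrap support, relative-rate dating against a
    rodent calibration interval). Every input has a matching synthetic-data
    generator with planted ground truth so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    IRanges,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
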