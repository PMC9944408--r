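Package: rileqtl
Title: Genetical Genomics in Recombinant Inbred Lines: Genotyping from
    RNA-Seq SNPs, eQTL Mapping and Trans-Band Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end genetical-genomics toolkit for biparental
    recombinant inbred line (RIL) populations assayed by RNA-seq under two
    environments. Builds physical and genetic (centimorgan) maps from
    RNA-seq SNP calls via sliding-bin genotyping, normalizes counts to TPM
    with log and ratio transforms, fits treatment and genotype-by-environment
    linear models, estimates broad-sense heritability and transgressive
    segregation with per-transcript permutation thresholds, maps expression
    QTL with a single-marker model and a permutation-based false discovery
    rate under dependency, classifies eQTL as cis or trans by distance and
    1.5-drop confidence intervals, detects trans-eQTL hotspots (trans-bands)
    by Poisson enrichment in 2-Mb bins, and runs hypergeometric set
    enrichment. Includes a synthetic RIL population and expression simulator
    with known ground truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Config/testthat/edition: 3
RoxygenNote: 7.3.3
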