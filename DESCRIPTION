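Package: magicmap
Title: Founder Mosaic Reconstruction and QTL Mapping for Multiparent
    Intercross Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genetic dissection of large multiparent (MAGIC-type)
    inter-cross populations: simulation of founder panels, intercross
    pedigrees and mosaic progeny genomes; reconstruction of founder
    identity-by-descent mosaics from SNP genotypes with a hidden Markov
    model; recombination-bin construction and bin-haplotype kinship;
    single-variant and bin-haplotype mixed-model association scans with
    REML likelihood-ratio tests and permutation thresholds; genome-wide
    pairwise epistasis scanning; multi-environment BLUP and broad-sense
    heritability; phenotype-driven collapse of founder alleles for QTL
    refinement; and drivers for tracing-power and mapping-power
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
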