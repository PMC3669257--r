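Package: seqgwas
Title: Sequence-Based GWAS of Genetic Architecture in Inbred Plant Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Kinship-corrected mixed-model association scanning (EMMAX/P3D)
    for panels of inbred (selfed) plant accessions, together with the
    statistics used to characterise the genetic architecture of complex
    traits: linkage-disequilibrium structure and minor-allele-frequency
    spectra of candidate SNPs, multiple regression of phenotypes on top
    candidates with backwards AIC simplification, phenotype-randomization
    nulls that correct the winner's curse (Beavis effect), gene tagging and
    tissue-specificity enrichment, and an in silico reduced-representation
    SNP-array experiment quantifying ascertainment bias relative to
    sequence-based candidates. Includes a synthetic genotype-phenotype
    generator with block-structured linkage disequilibrium, population
    structure, a skewed allele-frequency spectrum, and a randomized
    complete block phenotyping design, so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
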