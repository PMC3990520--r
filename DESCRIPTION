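Package: kinphase
Title: Pedigree-Aware Correction of Phased Haplotypes and Recombination
    Detection with a Parent-Child Gene-Flow HMM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines statistically phased haplotypes with pedigree
    information using a four-state hidden Markov model over parent-child
    gene flow. The model corrects switch errors in child and parental
    haplotypes, detects recombination events with posterior probabilities
    resolved to flanking heterozygous markers, and flags likely genotyping
    errors. Includes readers for SHAPEIT HAPS/SAMPLE, phased VCF, PLINK FAM
    and HapMap-style genetic maps; Mendelian-consistency QC; pedigree
    partitioning into duos and trios; a meiosis simulator with known truth
    (haploid pools, Poisson crossovers on sex-scaled maps, confusion-matrix
    genotyping error); and evaluation utilities including switch error,
    crossover TPR/FDR, Poisson count calibration and a hotspot-usage
    binomial GLM association test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
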