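Package: pedrec
Title: Locating Recombination Positions in Three-Generation Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers the grandparent-of-origin (GoO) of offspring alleles
    from unphased biallelic SNP genotypes of a three-generation pedigree
    and locates crossover positions along chromosomes. GoO inference
    matches 7-digit genotype strings (four grandparents, two parents,
    offspring; 0/1/2 coding) against an exhaustively enumerated dictionary
    of Mendelian-consistent transmission patterns. Crossovers are located
    per parental side with two change-point algorithms: the proportional
    difference (PD) scan over flanking windows of informative calls and
    the cumulative continuity score (CCS) run-length segmentation. Each
    reported position carries a precision estimate based on the reverse
    local density of informative alleles. Includes a pedigree genotype
    simulator with planted crossovers, genotyping error and missingness
    for validation, plus scaffold-to-chromosome coordinate mapping and a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
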