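Package: eiseniahyb
Title: Cytonuclear Inheritance and Asymmetrical Hybridization in Eisenia Earthworms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Exact Punnett-square enumeration and seeded forward simulation of
    cytonuclear inheritance in hybridizing Eisenia andrei and Eisenia fetida
    earthworms: maternal mitochondrial COI haplotype, two independently
    segregating nuclear loci (species-diagnostic 28S alleles and a dominant
    M-fluorophore allele) with parent-of-origin tracking, hermaphrodite
    selfing/outcrossing mixtures, mito-nuclear incompatibility of aF ova,
    hybrid sterility, and an alternative vertically transmitted symbiont
    mechanism. Includes synthetic coelomic-fluid fluorescence spectra with
    peak-based M-phenotype classification, pedigree-constrained M-genotype
    inference, maximum-likelihood estimation of selfing and hybridization
    rates from class counts, and likelihood comparison of the Mendelian and
    symbiont hypotheses on family phenotype counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
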