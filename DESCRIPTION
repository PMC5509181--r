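Package: ystrkit
Title: Y-STR Haplotype Diversity and Population Structure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic and population-genetic analysis of Y-chromosomal
    short tandem repeat (Y-STR) haplotype panels such as PowerPlex Y23. Parses
    and quality-controls haplotype tables (microvariant alleles, null alleles,
    DYS385a/b multi-copy genotypes, DYS389II adjustment), computes allele
    frequencies, Nei gene diversity and the forensic summary parameters
    (haplotype diversity, match probability, discrimination capacity), tests
    pairwise linkage disequilibrium between loci with a permutation G-test,
    estimates pairwise R_ST between populations by analysis of molecular
    variance (AMOVA) on squared repeat-count differences with permutation
    P-values and Bonferroni correction, and summarises population structure
    with neighbor-joining trees (Newick export, sum of branch lengths) and
    non-metric multidimensional scaling (Kruskal stress-1). A stepwise
    mutation model simulator generates structured synthetic populations with
    configurable divergence and genotyping artifacts so the whole pipeline can
    be exercised and calibrated without access to casework data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
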