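Package: pvpopgen
Title: Candidate-Gene Amplicon Population Genetics for Allotetraploid Switchgrass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for candidate-gene amplicon SNP analysis in
    allotetraploid switchgrass (Panicum virgatum) and similar allopolyploid panels:
    read-depth based zygosity calling and site/sample filtering; functional,
    frequency and subpopulation-prevalence classification of SNPs (including a
    BLOSUM62-based conservative/non-conservative rule for amino-acid changes);
    per-locus and per-contig diversity statistics (Ne, I, Ho, He, F, pi, Watterson's
    theta, haplotype diversity), Excoffier-Slatkin EM haplotype phasing, Tajima's D
    and Fu & Li's F/F* neutrality tests; Nei Gst, pairwise Fst and Nei distance,
    gene-flow estimates, and a three-level codominant AMOVA with permutation
    significance; a STRUCTURE-style admixture Gibbs sampler with LnP(D)-based K
    selection and PCoA; Mantel isolation-by-distance tests, per-individual local
    spatial autocorrelation (2D-LSA), bootstrapped UPGMA trees and calibration-based
    divergence dating; homoeologous K/N subgenome window profiles and contrasts; and
    a synthetic allotetraploid amplicon data generator with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    vcfR,
    Biostrings,
    ape,
    phangorn,
    vegan,
    geosphere
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
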