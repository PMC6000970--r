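test_that("coding effects come from codon translation", {
  expect_identical(coding_effect("GGT", 2, "C")$effect, "synonymous")
  expect_identical(coding_effect("GGT", 2, "C")$aa_ref, "G")
  # Gly -> Asp via middle-base change
  ce <- coding_effect("GGT", 1, "A")
  expect_identical(ce$effect, "nonsynonymous")
  expect_identical(ce$aa_alts, "D")
  # triallelic: both mutant residues reported (C -> F and C -> Y)
  ce2 <- coding_effect("TGT", 1, c("T", "A"))
  expect_identical(sort(ce2$aa_alts), c("F", "Y"))
  expect_identical(ce2$aa_ref, "C")
  # minus strand: reported alt is complemented before substitution
  ce3 <- coding_effect("GGT", 2, "G", strand = "-")
  expect_identical(ce3$aa_alts, "G")   # GGT -> GGC, still Gly
  expect_error(coding_effect("GGT", NA, "C"), "frame")
})

test_that("substitution-matrix rule separates conservative changes", {
  expect_identical(conservation_class("S", "Y"), "non_conservative")
  expect_identical(conservation_class("V", "I"), "conservative")
  expect_identical(conservation_class("A", "A"), "conservative")
  # score-0 pairs are non-conservative; score +1 pairs conservative
  expect_identical(conservation_class(c("F", "A", "N", "S"),
                                      c("L", "T", "K", "G")),
                   rep("non_conservative", 4))
  expect_identical(conservation_class(c("K", "R", "N", "V"),
                                      c("E", "Q", "S", "L")),
                   rep("conservative", 4))
  expect_error(conservation_class("B", "A"), "nonstandard")
})

test_that("wild-type assignment prefers the outgroup, then the majority", {
  wt <- assign_wild_type(c("G", "A"), c(0.3, 0.7), outgroup = "G")
  expect_identical(wt$wild_type_allele, "G")
  expect_identical(wt$source, "outgroup")
  expect_equal(wt$wildtype_freq, 0.3)

  wt2 <- assign_wild_type(c("G", "A"), c(0.7, 0.3), outgroup = "C")
  expect_identical(wt2$wild_type_allele, "G")
  expect_identical(wt2$source, "majority")

  wt3 <- assign_wild_type(c("G", "A"), c(0.5, 0.5), outgroup = NA)
  expect_identical(wt3$wild_type_allele, "G")  # reference tie-break
  expect_true(wt3$tie)
})

test_that("frequency classes partition [0,1] completely and disjointly", {
  expect_identical(frequency_class(c(0.9179, 0.33, 0.50)),
                   c("rare", "common", "balanced"))
  # boundaries
  expect_identical(frequency_class(c(0.25, 0.75, 0.40, 0.60)),
                   c("rare", "rare", "balanced", "balanced"))
  grid <- seq(0, 1, by = 0.005)
  cls <- frequency_class(grid)
  expect_true(all(cls %in% c("rare", "common", "balanced")))
  expect_error(frequency_class(1.2), "\\[0, 1\\]")
})

test_that("prevalence and diagnostic rules follow the frequency thresholds", {
  pv <- subpopulation_prevalence(c(C1 = 0.80, C2 = 0.10, C3 = 0.20))
  expect_identical(pv$status[pv$subpopulation == "C1"], "prevalent")
  pv2 <- subpopulation_prevalence(c(C1 = 0.60, C2 = 0.02, C3 = 0.04))
  expect_identical(pv2$status[pv2$subpopulation == "C1"], "diagnostic")
  pv3 <- subpopulation_prevalence(c(C1 = 0.5, C2 = 0.5, C3 = 0.5))
  expect_true(all(pv3$status == "none"))
  # presence in a single subpopulation is prevalent regardless of frequency
  pv4 <- subpopulation_prevalence(c(C1 = 0.10, C2 = 0, C3 = 0))
  expect_identical(pv4$status[1], "prevalent")
  expect_error(subpopulation_prevalence(c(C1 = 0.5)), "two subpopulations")
  # invariant to relabeling
  f <- c(A = 0.8, B = 0.1, C = 0.2)
  pv5 <- subpopulation_prevalence(f[c(2, 3, 1)])
  expect_identical(pv5$status[pv5$subpopulation == "A"], "prevalent")
})

test_that("ecotype predominance uses a two-proportion chi-square test", {
  expect_identical(ecotype_class(80, 100, 5, 100), "upland_predominant")
  expect_identical(ecotype_class(40, 100, 40, 100), "shared")
  expect_identical(ecotype_class(5, 100, 80, 100), "lowland_predominant")
  expect_warning(out <- ecotype_class(3, 0, 5, 100), "zero called")
  expect_identical(out, "shared")
})

test_that("planted ecotype-differential SNPs are recovered with high sensitivity", {
  set.seed(11)
  hits <- vapply(1:100, function(i) {
    k_up <- rbinom(1, 200, 0.8); k_low <- rbinom(1, 200, 0.05)
    ecotype_class(k_up, 200, k_low, 200) == "upland_predominant"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("classify_snps integrates effect, wild-type and prevalence", {
  sim <- simulate_dataset(sim_params(n_accessions = 5,
                                     samples_per_accession = 4,
                                     n_genes = 4, snps_per_contig = 8,
                                     seed = 12))
  ds <- apply_sample_filter(apply_site_filters(sim$dataset)$dataset)$dataset
  sub <- sim$truth$subpop[match(ds$samples$sample_id,
                                rownames(sim$truth$Q))]
  cls <- classify_snps(ds, reference = sim$reference, subpop = sub)
  expect_equal(nrow(cls), nrow(ds$loci))
  expect_true(all(cls$effect[ds$loci$region != "exon"] == "noncoding"))
  # conservation defined iff nonsynonymous
  expect_true(all((cls$conservation != "n/a") ==
                    (cls$effect == "nonsynonymous")))
  expect_true(all(cls$frequency_class %in% c("rare", "common", "balanced")))
  expect_true(all(cls$wildtype_freq >= 0 & cls$wildtype_freq <= 1))
})
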