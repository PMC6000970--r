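test_that("the generator is deterministic given its seed", {
  p <- sim_params(n_accessions = 4, samples_per_accession = 3, n_genes = 3,
                  snps_per_contig = 6, seed = 91)
  s1 <- simulate_dataset(p)
  s2 <- simulate_dataset(p)
  expect_identical(s1$dataset$depth, s2$dataset$depth)
  expect_identical(s1$dataset$alt_fraction, s2$dataset$alt_fraction)
  expect_identical(s1$truth$Q, s2$truth$Q)
  expect_identical(s1$reference, s2$reference)
  s3 <- simulate_dataset(sim_params(n_accessions = 4,
                                    samples_per_accession = 3, n_genes = 3,
                                    snps_per_contig = 6, seed = 92))
  expect_false(identical(s1$dataset$alt_fraction, s3$dataset$alt_fraction))
})

test_that("the emitted panel has the advertised shape and valid matrices", {
  sim <- simulate_dataset(sim_params(seed = 93))
  ds <- sim$dataset
  expect_equal(nrow(ds$samples), 360)
  expect_equal(dplyr::n_distinct(ds$loci$contig_id), 21)
  expect_equal(nrow(ds$loci), 21 * 12)
  expect_true(all(ds$loci$region %in%
                    c("exon", "intron", "UTR5", "UTR3")))
  expect_true(all(!is.na(ds$loci$codon_frame[ds$loci$region == "exon"])))
  expect_true(all(is.na(ds$alt_fraction) == (ds$depth == 0)))
  expect_true(all(table(ds$loci$gene[!duplicated(ds$loci$contig_id)]) <= 2))
  # triallelic loci carry two alternates and a second-alt read share
  tri <- grepl(",", ds$loci$alt_alleles)
  if (any(tri)) {
    expect_true(max(ds$alt2_fraction[, tri]) > 0)
    expect_true(all(ds$alt2_fraction[, !tri] == 0))
  }
})

test_that("panmictic simulation yields near-zero differentiation", {
  set.seed(94)
  sim <- simulate_dataset(sim_params(n_subpops = 2, divergence_F = 0,
                                     n_accessions = 10,
                                     samples_per_accession = 10,
                                     n_genes = 8, snps_per_contig = 13,
                                     missing_rate = 0, seed = 94))
  ds <- sim$dataset
  grp <- rep(c("A", "B"), length.out = nrow(ds$samples))
  pw <- pairwise_differentiation(ds, grp)
  expect_lt(abs(unname(pw$fst["A", "B"])), 0.02)
})

test_that("realized frequencies track Balding-Nichols expectations at large n", {
  set.seed(95)
  p <- sim_params(n_subpops = 2, divergence_F = 0.2, n_accessions = 20,
                  samples_per_accession = 50, n_genes = 2,
                  snps_per_contig = 10, missing_rate = 0, mean_depth = 60,
                  admixture_alpha = 0.01, seed = 95)
  sim <- simulate_dataset(p)
  ds <- sim$dataset
  # compare realized within-subpop alt frequency to the truth frequencies
  spop <- sim$truth$subpop
  pure <- apply(sim$truth$Q, 1, max) > 0.95
  d <- dosage(ds)[pure, ]
  pf_hat <- do.call(rbind, lapply(split(seq_len(nrow(d)), spop[pure]),
                                  function(i) colMeans(d[i, ], na.rm = TRUE)))
  pf_true <- do.call(cbind, sim$truth$subpop_freqs)
  rows <- as.integer(sub("C", "", rownames(pf_hat)))
  err <- abs(pf_hat - pf_true[rows, ])
  expect_lt(mean(err, na.rm = TRUE), 0.06)
})

test_that("truth_report returns zero error when handed the truth itself", {
  sim <- simulate_dataset(sim_params(n_accessions = 4,
                                     samples_per_accession = 3,
                                     n_genes = 3, snps_per_contig = 6,
                                     seed = 96))
  fake_fit <- structure(list(K = ncol(sim$truth$Q), Q = sim$truth$Q,
                             P = NULL, lnPD_per_run = 0, chosen_run = 1),
                        class = "pvp_admixture")
  tr <- truth_report(sim$truth, admixture = fake_fit, fst = sim$truth$fst)
  expect_equal(tr$value[tr$metric == "q_rmse"], 0)
  expect_equal(tr$value[tr$metric == "fst_rmse"], 0)
  expect_error(truth_report(sim$truth,
                            admixture = structure(list(Q = sim$truth$Q[1:3, ]),
                                                  class = "pvp_admixture")),
               "differ")
})
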