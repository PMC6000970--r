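test_that("zygosity calling follows the fraction windows and boundaries", {
  expect_identical(call_genotype_state(c(0.10, 0.50, 0.30, 0.80, NA)),
                   c("hom_ref", "het", "ambiguous", "hom_alt", "missing"))
  # boundary policy: 0.25/0.75 are not homozygous; 0.40/0.60 are het
  expect_identical(call_genotype_state(c(0.25, 0.75, 0.40, 0.60)),
                   c("ambiguous", "ambiguous", "het", "het"))
  expect_error(call_genotype_state(1.2), "\\[0, 1\\]")
  m <- call_genotype_state(matrix(c(0.1, 0.5, NA, 0.9), 2, 2))
  expect_true(is.matrix(m))
})

test_that("adjacent runs are removed whole and the MAF window applies", {
  set.seed(2)
  d <- matrix(rep(c(0, 0.5, 1), length.out = 60), 10, 6)
  ds <- ds_from_dosage(d)
  ds$loci$position <- c(10, 50, 100, 101, 200, 300)
  out <- apply_site_filters(ds)
  expect_equal(out$report$n_adjacent_removed, 2)
  expect_equal(nrow(out$dataset$loci), 4)
  expect_false(any(out$dataset$loci$position %in% c(100, 101)))

  # site with alt frequency 0.03 goes by the MAF rule
  d2 <- matrix(0, 50, 2); d2[1:3, 1] <- 0.5; d2[, 2] <- 0.5
  out2 <- apply_site_filters(ds_from_dosage(d2))
  expect_equal(out2$report$n_maf_removed, 1)
  expect_equal(out2$dataset$loci$locus_id, ds_from_dosage(d2)$loci$locus_id[2])
})

test_that("report counts match brute-force per-rule tallies on a toy panel", {
  set.seed(33)
  n <- 10; L <- 10
  d <- matrix(sample(c(0, 0.5, 1), n * L, TRUE, prob = c(.5, .3, .2)), n, L)
  depth <- matrix(sample(c(0L, 2L, 30L), n * L, TRUE,
                         prob = c(.05, .1, .85)), n, L)
  af <- ifelse(depth > 0, d, NA)
  ds <- snp_dataset(toy_samples(n), toy_loci(L), depth, af)
  ds$loci$position <- c(5, 6, 20, 30, 40, 50, 60, 70, 80, 90)
  out <- apply_site_filters(ds)
  rep <- out$report

  # brute force, replaying the documented order independently
  keep <- rep(TRUE, L)
  adj <- c(1, 2)                                  # positions 5,6
  n_adj <- length(adj); keep[adj] <- FALSE
  st <- call_genotype_state(af)
  st[depth > 0 & depth < 3] <- "missing"
  n_masked <- sum(depth[, keep] > 0 & depth[, keep] < 3 &
                    call_genotype_state(af[, keep]) != "missing")
  dos <- matrix(NA_real_, n, L)
  dos[st == "hom_ref"] <- 0; dos[st == "het"] <- 0.5; dos[st == "hom_alt"] <- 1
  miss <- colMeans(is.na(dos))
  n_miss <- sum(keep & miss >= 0.2); keep[miss >= 0.2] <- FALSE
  fr <- colMeans(dos, na.rm = TRUE)
  n_maf <- sum(keep & (fr < 0.05 | fr > 0.95)); keep[fr < 0.05 | fr > 0.95] <- FALSE

  expect_equal(rep$n_adjacent_removed, n_adj)
  expect_equal(rep$n_depth_masked_calls, n_masked)
  expect_equal(rep$n_missingness_removed, n_miss)
  expect_equal(rep$n_maf_removed, n_maf)
  expect_equal(rep$n_retained, sum(keep))
  # every removed variant lands in exactly one category
  expect_equal(rep$n_input_variants - rep$n_retained,
               rep$n_indels_removed + rep$n_adjacent_removed +
                 rep$n_missingness_removed + rep$n_maf_removed)
})

test_that("site filtering is idempotent", {
  set.seed(4)
  sim <- simulate_dataset(sim_params(n_accessions = 4,
                                     samples_per_accession = 4,
                                     n_genes = 3, snps_per_contig = 8,
                                     seed = 4))
  once <- apply_site_filters(sim$dataset)
  twice <- apply_site_filters(once$dataset)
  expect_equal(nrow(twice$dataset$loci), nrow(once$dataset$loci))
  expect_equal(twice$report$n_maf_removed +
                 twice$report$n_missingness_removed +
                 twice$report$n_adjacent_removed, 0)
  expect_identical(unname(twice$dataset$state), unname(once$dataset$state))
})

test_that("sample filter drops exactly the high-missingness genotypes", {
  set.seed(5)
  d <- matrix(0.5, 20, 20)
  d[1, 1:7] <- NA   # 35% missing -> dropped
  d[2, 1:6] <- NA   # 30% missing -> retained (rule is strictly greater)
  ds <- ds_from_dosage(d)
  out <- apply_sample_filter(ds)
  expect_equal(out$report$n_samples_removed, 1)
  expect_false("s001" %in% out$dataset$samples$sample_id)
  expect_true("s002" %in% out$dataset$samples$sample_id)
  # planted dropout sample in a simulated panel is the one removed
  sim <- simulate_dataset(sim_params(n_accessions = 3,
                                     samples_per_accession = 4,
                                     n_genes = 3, snps_per_contig = 8,
                                     missing_rate = 0, seed = 6))
  ds2 <- sim$dataset
  ds2$depth[5, seq_len(ceiling(0.5 * ncol(ds2$depth)))] <- 0L
  ds2$alt_fraction[5, seq_len(ceiling(0.5 * ncol(ds2$depth)))] <- NA
  ds2$state <- call_genotype_state(ds2$alt_fraction)
  out2 <- apply_sample_filter(apply_site_filters(ds2)$dataset)
  gone <- setdiff(ds2$samples$sample_id, out2$dataset$samples$sample_id)
  expect_identical(gone, ds2$samples$sample_id[5])

  d3 <- matrix(NA_real_, 3, 4)
  expect_error(apply_sample_filter(ds_from_dosage(d3)), "all 3 samples")
})
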