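test_that("dataset construction enforces the call-matrix invariants", {
  set.seed(1)
  d <- matrix(c(0, 0.5, 1, NA), 2, 2)
  ds <- ds_from_dosage(d)
  expect_s3_class(ds, "snp_dataset")
  # state missing exactly where depth == 0
  expect_identical(ds$state == "missing", ds$depth == 0)
  expect_true(all(is.na(ds$alt_fraction) == (ds$depth == 0)))
  # alt_fraction in [0,1] wherever depth > 0
  af <- ds$alt_fraction[ds$depth > 0]
  expect_true(all(af >= 0 & af <= 1))

  expect_error(snp_dataset(toy_samples(2), toy_loci(2),
                           depth = matrix(1, 2, 2),
                           alt_fraction = matrix(1.5, 2, 2)),
               "\\[0, 1\\]")
  bad <- toy_samples(2); bad$latitude[1] <- 95
  expect_error(snp_dataset(bad, toy_loci(2), matrix(1, 2, 2),
                           matrix(0.5, 2, 2)), "coordinates")
})

test_that("AD arithmetic, dosage coding and long view agree", {
  ds <- ds_from_dosage(matrix(c(0.5, 0, 1, NA), 2, 2), depth = 20L)
  expect_equal(unname(dosage(ds)[1, 1]), 0.5)  # AD 10,10 -> het
  tb <- tibble::as_tibble(ds)
  expect_equal(nrow(tb), 4)
  expect_setequal(unique(tb$state), c("het", "hom_ref", "hom_alt", "missing"))
})

test_that("written panels round-trip through VCF/metadata/annotation", {
  sim <- simulate_dataset(sim_params(n_accessions = 4,
                                     samples_per_accession = 3,
                                     n_genes = 3, snps_per_contig = 6,
                                     seed = 42))
  dir <- withr::local_tempdir()
  write_dataset(sim$dataset, dir, reference = sim$reference)
  ds2 <- load_dataset(file.path(dir, "variants.vcf"),
                      file.path(dir, "metadata.tsv"),
                      file.path(dir, "annotation.tsv"),
                      reference_path = file.path(dir, "reference.fasta"),
                      outgroup_path = file.path(dir, "outgroup.tsv"))
  expect_equal(dim(ds2), dim(sim$dataset))
  expect_equal(unname(ds2$depth), unname(sim$dataset$depth))
  expect_equal(unname(ds2$alt_fraction), unname(sim$dataset$alt_fraction),
               tolerance = 1e-12)
  expect_identical(unname(ds2$state), unname(sim$dataset$state))
  expect_equal(ds2$loci$position, sim$dataset$loci$position)
  expect_equal(ds2$loci$region, sim$dataset$loci$region)
  expect_equal(ds2$loci$codon_frame, sim$dataset$loci$codon_frame)
  expect_equal(ds2$loci$outgroup_allele, sim$dataset$loci$outgroup_allele)
  # reference sequences attached and identical
  expect_identical(unname(attr(ds2, "reference")), unname(sim$reference))

  # re-export of the loaded panel is byte-identical
  dir2 <- withr::local_tempdir()
  write_dataset(ds2, dir2)
  expect_identical(readLines(file.path(dir, "variants.vcf")),
                   readLines(file.path(dir2, "variants.vcf")))
})

test_that("a VCF sample missing from metadata is a named hard error", {
  sim <- simulate_dataset(sim_params(n_accessions = 2,
                                     samples_per_accession = 2,
                                     n_genes = 2, snps_per_contig = 4,
                                     seed = 9))
  dir <- withr::local_tempdir()
  write_dataset(sim$dataset, dir)
  meta <- readr::read_tsv(file.path(dir, "metadata.tsv"),
                          show_col_types = FALSE)
  readr::write_tsv(meta[-2, ], file.path(dir, "metadata.tsv"))
  expect_error(load_dataset(file.path(dir, "variants.vcf"),
                            file.path(dir, "metadata.tsv"),
                            file.path(dir, "annotation.tsv")),
               meta$sample_id[2])
})

test_that("loci outside annotated intervals fall back to intergenic", {
  sim <- simulate_dataset(sim_params(n_accessions = 2,
                                     samples_per_accession = 2,
                                     n_genes = 2, snps_per_contig = 4,
                                     seed = 10))
  dir <- withr::local_tempdir()
  write_dataset(sim$dataset, dir)
  ann <- readr::read_tsv(file.path(dir, "annotation.tsv"),
                         show_col_types = FALSE)
  readr::write_tsv(ann[-1, ], file.path(dir, "annotation.tsv"))
  expect_warning(
    ds2 <- load_dataset(file.path(dir, "variants.vcf"),
                        file.path(dir, "metadata.tsv"),
                        file.path(dir, "annotation.tsv")),
    "intergenic")
  expect_identical(ds2$loci$region[1], "intergenic")
})

test_that("export_tables writes all five layouts, even when empty", {
  dir <- withr::local_tempdir()
  export_tables(list(), dir)
  for (f in c("gene_diversity.tsv", "snp_classification.tsv",
              "subpop_diversity.tsv", "pairwise_differentiation.csv",
              "amova.tsv")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  # the AMOVA layout exposes the standard columns
  hdr <- names(readr::read_tsv(file.path(dir, "amova.tsv"),
                               show_col_types = FALSE))
  expect_true(all(c("df", "SS", "MS", "Est.Var", "%") %in% hdr))
})
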