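#' Curated worked-example tables
#'
#' Small curated tables for a 12-gene, 21-contig switchgrass candidate-gene
#' amplicon panel, shipped as plain text under `extdata` and used in the
#' worked examples and consistency checks:
#'
#' * `example_aa_substitutions()` - 49 nonsynonymous SNPs with their
#'   reference/alternate/outgroup amino acids, the resolved wild-type and
#'   mutant residues with panel frequencies (percent), and the printed
#'   conservative / non-conservative label.
#' * `example_gene_summary()` - per-contig summary in the standard per-gene
#'   diversity layout: sample count, alignment and coding lengths,
#'   segregating-site breakdown (non-coding / synonymous / conservative /
#'   non-conservative), SNP density `d`, `pi` and Watterson's theta
#'   (x 10^-3, with SDs), haplotype count and diversity, and Tajima's D.
#' * `example_amova_components()` - three AMOVA tables (latitude bins,
#'   accessions, genetic subpopulations) with df, SS, MS, estimated
#'   variance components and percentages.
#'
#' @return A tibble.
#' @name example_tables
NULL

read_curated <- function(file) {
  readr::read_tsv(system.file("extdata", file, package = "pvpopgen"),
                  show_col_types = FALSE)
}

#' @rdname example_tables
#' @export
example_aa_substitutions <- function() read_curated("aa_substitutions_curated.tsv")

#' @rdname example_tables
#' @export
example_gene_summary <- function() read_curated("gene_diversity_curated.tsv")

#' @rdname example_tables
#' @export
example_amova_components <- function() read_curated("amova_components_curated.tsv")
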