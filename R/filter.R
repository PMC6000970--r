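#' Call zygosity state from an alternate-allele read fraction
#'
#' Read-backed zygosity calling for a disomic (per-subgenome) genotype.
#' Fractions below 0.25 are homozygous reference and above 0.75 homozygous
#' alternate; the 0.40-0.60 band (inclusive) is heterozygous. The gaps
#' `[0.25, 0.40)` and `(0.60, 0.75]` fall in neither defined interval and are
#' called `ambiguous`; ambiguous calls behave as missing in every downstream
#' allele-frequency computation. `NA` fractions (zero depth) are `missing`.
#'
#' @param alt_fraction Numeric vector or matrix of summed alternate-allele
#'   read fractions in `[0, 1]`, `NA` allowed.
#' @return Character vector/matrix of states: `hom_ref`, `het`, `hom_alt`,
#'   `ambiguous`, `missing`.
#' @examples
#' call_genotype_state(c(0.10, 0.50, 0.30, 0.80, NA))
#' @export
call_genotype_state <- function(alt_fraction) {
  x <- alt_fraction
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    abort("alt_fraction values must lie in [0, 1]")
  }
  out <- rep("ambiguous", length(x))
  out[is.na(x)] <- "missing"
  out[!is.na(x) & x < 0.25] <- "hom_ref"
  out[!is.na(x) & x > 0.75] <- "hom_alt"
  out[!is.na(x) & x >= 0.40 & x <= 0.60] <- "het"
  if (is.matrix(x)) out <- matrix(out, nrow(x), ncol(x), dimnames = dimnames(x))
  out
}

new_filter_report <- function(n_input) {
  tibble(
    n_input_variants = n_input,
    n_indels_removed = 0L, n_adjacent_removed = 0L,
    n_depth_masked_calls = 0L, n_missingness_removed = 0L,
    n_maf_removed = 0L, n_samples_removed = 0L,
    n_retained = n_input
  )
}

#' Apply the site-level filter cascade
#'
#' Filters are applied in a fixed, logged order so that report counts are
#' reproducible: (1) INDEL records dropped; (2) every member of a run of
#' variants at immediately adjacent positions on the same contig dropped
#' (adjacent calls are treated as biologically unlikely alignment artefacts);
#' (3) calls with read depth below `min_depth` masked to missing; (4) sites
#' with at least `max_missing` missing calls dropped (ambiguous-zone calls
#' count as missing); (5) sites with population alternate-allele frequency
#' below `maf_lo` or above `maf_hi` dropped. The population frequency is the
#' mean alt dosage (0 / 0.5 / 1) over non-missing called genotypes, computed
#' after depth masking. Each removed variant is tallied in exactly one
#' report category (the first rule that removes it).
#'
#' @param dataset An [snp_dataset()].
#' @param maf_lo,maf_hi Population alt-frequency bounds (defaults 0.05, 0.95).
#' @param max_missing Maximum tolerated per-site missing fraction (default
#'   0.20; sites at or above the bound are dropped).
#' @param min_depth Minimum read depth for a call to stand (default 3).
#' @return List with `dataset` (filtered) and `report` (one-row tibble).
#' @export
apply_site_filters <- function(dataset, maf_lo = 0.05, maf_hi = 0.95,
                               max_missing = 0.20, min_depth = 3) {
  stopifnot(inherits(dataset, "snp_dataset"))
  if (nrow(dataset$loci) == 0 || nrow(dataset$samples) == 0) {
    abort("cannot filter an empty dataset")
  }
  rep0 <- new_filter_report(nrow(dataset$loci))
  ds <- dataset

  # 1. INDELs: any allele longer than one base
  is_indel <- nchar(ds$loci$ref_allele) > 1 |
    map_lgl(strsplit(ds$loci$alt_alleles, ","),
            function(a) any(nchar(trimws(a)) > 1))
  rep0$n_indels_removed <- sum(is_indel)
  if (any(is_indel)) ds <- subset_dataset(ds, loci = !is_indel)

  # 2. adjacency: whole runs of consecutive positions go
  adj <- ds$loci |>
    mutate(.row = dplyr::row_number()) |>
    arrange(.data$contig_id, .data$position) |>
    group_by(.data$contig_id) |>
    mutate(.adj = (c(Inf, diff(.data$position)) == 1) |
                  (c(diff(.data$position), Inf) == 1)) |>
    ungroup() |>
    arrange(.data$.row)
  rep0$n_adjacent_removed <- sum(adj$.adj)
  if (any(adj$.adj)) ds <- subset_dataset(ds, loci = !adj$.adj)

  # 3. depth masking
  mask <- ds$depth > 0 & ds$depth < min_depth &
    ds$state %in% c("hom_ref", "het", "hom_alt", "ambiguous")
  rep0$n_depth_masked_calls <- sum(mask)
  ds$state[mask] <- "missing"

  # 4. site missingness (ambiguous counts as missing, as in dosage())
  miss_frac <- colMeans(is.na(dosage(ds)))
  drop_miss <- miss_frac >= max_missing
  rep0$n_missingness_removed <- sum(drop_miss)
  if (any(drop_miss)) ds <- subset_dataset(ds, loci = !drop_miss)

  # 5. population allele frequency
  af <- allele_freqs(ds)$alt_freq
  drop_maf <- is.na(af) | af < maf_lo | af > maf_hi
  rep0$n_maf_removed <- sum(drop_maf)
  if (any(drop_maf)) ds <- subset_dataset(ds, loci = !drop_maf)

  rep0$n_retained <- nrow(ds$loci)
  list(dataset = ds, report = rep0)
}

#' Drop samples with excessive missing data
#'
#' Samples whose fraction of missing calls (missing or ambiguous) exceeds
#' `max_sample_missing` are removed. Intended to run after
#' [apply_site_filters()].
#'
#' @param dataset An [snp_dataset()].
#' @param max_sample_missing Maximum tolerated missing fraction per sample
#'   (default 0.30; strictly above the bound is dropped).
#' @return List with `dataset` and `report`.
#' @export
apply_sample_filter <- function(dataset, max_sample_missing = 0.30) {
  stopifnot(inherits(dataset, "snp_dataset"))
  miss_frac <- rowMeans(is.na(dosage(dataset)))
  drop <- miss_frac > max_sample_missing
  if (all(drop)) {
    abort(sprintf(
      "all %d samples exceed %.0f%% missing data; check depth and filters",
      length(drop), 100 * max_sample_missing))
  }
  rep0 <- new_filter_report(nrow(dataset$loci))
  rep0$n_samples_removed <- sum(drop)
  ds <- if (any(drop)) subset_dataset(dataset, samples = !drop) else dataset
  list(dataset = ds, report = rep0)
}
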