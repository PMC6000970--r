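#' SNP dataset container
#'
#' Bundles the three ingredients of an amplicon SNP panel: a sample metadata
#' table, a locus annotation table, and the per-call matrices (total read
#' depth, summed alternate-allele read fraction, optional secondary-alternate
#' fraction for triallelic sites, and the called zygosity state).
#'
#' Matrices are samples x loci, with rownames = `samples$sample_id` and
#' colnames = `loci$locus_id`. `alt_fraction` is `NA` exactly where
#' `depth == 0`. Triallelic sites keep the summed non-reference fraction in
#' `alt_fraction` and the secondary allele's share in `alt2_fraction` so the
#' per-allele split is recoverable (`alt1 = alt_fraction - alt2_fraction`).
#'
#' @param samples Tibble with columns `sample_id`, `accession_id`, `ecotype`
#'   (`upland`/`lowland`/`unknown`), `ploidy` (`4x`/`8x`/`mixed`/`unknown`),
#'   `latitude`, `longitude`.
#' @param loci Tibble with columns `locus_id`, `contig_id`, `gene`,
#'   `chromosome`, `subgenome` (`K`/`N`/`unknown`), `position` (1-based),
#'   `ref_allele`, `alt_alleles` (comma-separated, 1-2 alleles), `region`
#'   (`exon`/`intron`/`UTR5`/`UTR3`/`intergenic`), `codon_frame`
#'   (0-2 or `NA`), `outgroup_allele` (nucleotide or `NA`).
#' @param depth Integer matrix of total read depth.
#' @param alt_fraction Numeric matrix in `[0, 1]`, `NA` where depth is 0.
#' @param alt2_fraction Optional numeric matrix (secondary alt share).
#' @param state Optional character matrix of zygosity states; computed with
#'   [call_genotype_state()] when absent.
#'
#' @return An object of class `snp_dataset`.
#' @export
snp_dataset <- function(samples, loci, depth, alt_fraction,
                        alt2_fraction = NULL, state = NULL) {
  samples <- as_tibble(samples)
  loci <- as_tibble(loci)
  need_s <- c("sample_id", "accession_id", "ecotype", "ploidy",
              "latitude", "longitude")
  if (!all(need_s %in% names(samples))) {
    abort(paste0("samples is missing column(s): ",
                 paste(setdiff(need_s, names(samples)), collapse = ", ")))
  }
  need_l <- c("locus_id", "contig_id", "gene", "chromosome", "subgenome",
              "position", "ref_allele", "alt_alleles", "region",
              "codon_frame", "outgroup_allele")
  if (!all(need_l %in% names(loci))) {
    abort(paste0("loci is missing column(s): ",
                 paste(setdiff(need_l, names(loci)), collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) abort("sample_id values must be unique")
  if (anyDuplicated(loci$locus_id)) abort("locus_id values must be unique")
  ok_lat <- is.na(samples$latitude) |
    (samples$latitude >= -90 & samples$latitude <= 90)
  ok_lon <- is.na(samples$longitude) |
    (samples$longitude >= -180 & samples$longitude <= 180)
  if (!all(ok_lat) || !all(ok_lon)) abort("coordinates out of range")

  depth <- as.matrix(depth)
  alt_fraction <- as.matrix(alt_fraction)
  n <- nrow(samples); L <- nrow(loci)
  if (!all(dim(depth) == c(n, L)) || !all(dim(alt_fraction) == c(n, L))) {
    abort("matrix dimensions must be samples x loci")
  }
  if (any(depth < 0, na.rm = TRUE)) abort("depth must be non-negative")
  depth[is.na(depth)] <- 0L
  bad <- which(depth == 0 & !is.na(alt_fraction))
  if (length(bad)) alt_fraction[bad] <- NA_real_
  bad <- which(depth > 0 & is.na(alt_fraction))
  if (length(bad)) abort("alt_fraction missing where depth > 0")
  if (any(alt_fraction < 0 | alt_fraction > 1, na.rm = TRUE)) {
    abort("alt_fraction must lie in [0, 1]")
  }
  dimnames(depth) <- dimnames(alt_fraction) <-
    list(samples$sample_id, loci$locus_id)
  if (!is.null(alt2_fraction)) {
    alt2_fraction <- as.matrix(alt2_fraction)
    if (!all(dim(alt2_fraction) == c(n, L))) abort("alt2_fraction dims wrong")
    dimnames(alt2_fraction) <- dimnames(depth)
  }
  if (is.null(state)) {
    state <- call_genotype_state(alt_fraction)
  } else {
    state <- as.matrix(state)
    dimnames(state) <- dimnames(depth)
  }

  structure(
    list(samples = samples, loci = loci, depth = depth,
         alt_fraction = alt_fraction, alt2_fraction = alt2_fraction,
         state = state),
    class = "snp_dataset"
  )
}

#' @export
print.snp_dataset <- function(x, ...) {
  n_called <- mean(x$state %in% c("hom_ref", "het", "hom_alt"))
  cat(sprintf(
    "<snp_dataset> %d samples x %d loci (%d contigs, %d genes); %.1f%% called\n",
    nrow(x$samples), nrow(x$loci),
    dplyr::n_distinct(x$loci$contig_id), dplyr::n_distinct(x$loci$gene),
    100 * n_called))
  invisible(x)
}

#' @export
dim.snp_dataset <- function(x) c(nrow(x$samples), nrow(x$loci))

#' Long-format view of the per-call matrices
#'
#' @param x An `snp_dataset`.
#' @param ... Unused.
#' @return Tibble with one row per sample x locus call.
#' @export
as_tibble.snp_dataset <- function(x, ...) {
  tibble(
    sample_id = rep(x$samples$sample_id, times = nrow(x$loci)),
    locus_id = rep(x$loci$locus_id, each = nrow(x$samples)),
    depth = as.vector(x$depth),
    alt_fraction = as.vector(x$alt_fraction),
    state = as.vector(x$state)
  )
}

#' Genotype dosage matrix
#'
#' Alternate-allele dosage per call: `hom_ref` = 0, `het` = 0.5,
#' `hom_alt` = 1. Ambiguous-zone and missing calls are `NA`, so every
#' downstream allele-frequency computation automatically excludes them.
#'
#' @param x An `snp_dataset`.
#' @return Numeric samples x loci matrix.
#' @export
dosage <- function(x) {
  stopifnot(inherits(x, "snp_dataset"))
  d <- matrix(NA_real_, nrow(x$state), ncol(x$state), dimnames = dimnames(x$state))
  d[x$state == "hom_ref"] <- 0
  d[x$state == "het"] <- 0.5
  d[x$state == "hom_alt"] <- 1
  d
}

#' Per-locus alternate-allele frequency
#'
#' Mean alt dosage over non-missing called genotypes, overall or within
#' groups.
#'
#' @param x An `snp_dataset`.
#' @param by Optional vector of group labels, one per sample.
#' @return Tibble with `locus_id`, optional `group`, `alt_freq`, `n_called`.
#' @export
allele_freqs <- function(x, by = NULL) {
  d <- dosage(x)
  if (is.null(by)) {
    tibble(
      locus_id = colnames(d),
      alt_freq = colMeans(d, na.rm = TRUE),
      n_called = colSums(!is.na(d))
    )
  } else {
    stopifnot(length(by) == nrow(d))
    purrr::map_dfr(split(seq_len(nrow(d)), by), function(idx) {
      dd <- d[idx, , drop = FALSE]
      tibble(locus_id = colnames(d),
             alt_freq = colMeans(dd, na.rm = TRUE),
             n_called = colSums(!is.na(dd)))
    }, .id = "group")
  }
}

#' Subset a dataset by samples and/or loci
#'
#' @param x An `snp_dataset`.
#' @param samples,loci Logical or index vectors (or IDs) selecting what to
#'   keep.
#' @return A new `snp_dataset`.
#' @export
subset_dataset <- function(x, samples = NULL, loci = NULL) {
  si <- seq_len(nrow(x$samples)); li <- seq_len(nrow(x$loci))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$samples$sample_id)
          else si[samples]
  }
  if (!is.null(loci)) {
    li <- if (is.character(loci)) match(loci, x$loci$locus_id) else li[loci]
  }
  if (anyNA(si) || anyNA(li)) abort("unknown sample or locus selection")
  snp_dataset(
    samples = x$samples[si, , drop = FALSE],
    loci = x$loci[li, , drop = FALSE],
    depth = x$depth[si, li, drop = FALSE],
    alt_fraction = x$alt_fraction[si, li, drop = FALSE],
    alt2_fraction = if (!is.null(x$alt2_fraction))
      x$alt2_fraction[si, li, drop = FALSE],
    state = x$state[si, li, drop = FALSE]
  )
}
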