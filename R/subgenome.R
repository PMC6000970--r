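#' Windowed SNP profile along a contig
#'
#' Counts SNPs (and optionally per-group allele frequencies) in
#' non-overlapping windows tiling the analyzed region from position 1.
#'
#' @param loci Tibble of loci for one contig (needs `position`; optionally
#'   `locus_id`).
#' @param contig_length Length of the analyzed region in bp.
#' @param bin Window size in bp (default 100).
#' @param group_freqs Optional tibble from [allele_freqs()] with `group`,
#'   `locus_id`, `alt_freq` to average per window.
#' @return Tibble with `window_start`, `window_end`, `snp_count` and, when
#'   group frequencies are given, one mean-frequency column per group.
#' @export
window_variant_profile <- function(loci, contig_length, bin = 100,
                                   group_freqs = NULL) {
  if (bin <= 0) abort("bin size must be positive")
  if (nrow(loci) && any(loci$position < 1 | loci$position > contig_length)) {
    abort("locus positions outside contig bounds")
  }
  starts <- seq(1, contig_length, by = bin)
  win <- tibble(
    window_start = starts,
    window_end = pmin(starts + bin - 1, contig_length)
  )
  idx <- if (nrow(loci)) ((loci$position - 1) %/% bin) + 1 else integer()
  win$snp_count <- tabulate(idx, nbins = nrow(win))
  if (!is.null(group_freqs) && nrow(loci)) {
    gf <- loci |>
      mutate(.win = idx) |>
      select("locus_id", ".win") |>
      left_join(group_freqs, by = "locus_id") |>
      group_by(.data$.win, .data$group) |>
      summarise(mean_alt_freq = mean(.data$alt_freq, na.rm = TRUE),
                .groups = "drop") |>
      tidyr::pivot_wider(names_from = "group",
                         values_from = "mean_alt_freq",
                         names_prefix = "freq_")
    win <- left_join(win |> mutate(.win = dplyr::row_number()),
                     gf, by = ".win") |> select(-".win")
  }
  win
}

#' Contrast homoeologous K/N gene copies
#'
#' Percentage of polymorphic loci per subgenome for one gene, computed on
#' the shared (overlapping) homoeologous region when the overlap is known.
#' Genes with mapping data in fewer than `min_mapped` of the accessions are
#' excluded upstream (see [homoeolog_contrast_table()]).
#'
#' @param loci_k,loci_n Locus tibbles for the K and N copies (columns
#'   `position`, `is_polymorphic`).
#' @param region_k,region_n Two-element integer vectors (start, end) of the
#'   analyzed region on each copy; the shared region is mapped through the
#'   pairing so positions are comparable.
#' @param gene Gene label for the output row.
#' @return One-row tibble: `gene`, `pctP_K`, `pctP_N`, `delta`,
#'   `n_loci_K`, `n_loci_N`, `shared_region_only`.
#' @export
homoeolog_contrast <- function(loci_k, loci_n, region_k = NULL,
                               region_n = NULL, gene = NA_character_) {
  shared <- !is.null(region_k) && !is.null(region_n)
  if (shared) {
    span <- min(region_k[2] - region_k[1], region_n[2] - region_n[1])
    if (span < 0) {
      warn("no shared homoeologous region; contrasting full regions")
      shared <- FALSE
    } else {
      loci_k <- filter(loci_k, .data$position >= region_k[1],
                       .data$position <= region_k[1] + span)
      loci_n <- filter(loci_n, .data$position >= region_n[1],
                       .data$position <= region_n[1] + span)
    }
  }
  pct <- function(df) if (nrow(df)) 100 * mean(df$is_polymorphic) else 0
  tibble(
    gene = gene,
    pctP_K = pct(loci_k), pctP_N = pct(loci_n),
    delta = pct(loci_k) - pct(loci_n),
    n_loci_K = nrow(loci_k), n_loci_N = nrow(loci_n),
    shared_region_only = shared
  )
}

#' Per-gene homoeolog contrast table
#'
#' Builds the per-gene K-vs-N polymorphism contrast across a dataset. Only
#' genes with both subgenome copies present and with called data in more
#' than `min_mapped` of the accessions are contrasted. The percentage of
#' polymorphic loci is taken over each copy's retained SNPs (every retained
#' SNP is polymorphic by construction, so the contrast uses SNP counts
#' normalized by the analyzed region length when lengths are supplied).
#'
#' @param dataset A filtered [snp_dataset()].
#' @param contig_lengths Optional named vector of analyzed-region lengths
#'   per contig; when supplied the contrast is SNP density (percent) rather
#'   than raw polymorphic-locus percentage.
#' @param min_mapped Minimum fraction of accessions with data (default 0.8).
#' @return Tibble with one row per contrasted gene.
#' @export
homoeolog_contrast_table <- function(dataset, contig_lengths = NULL,
                                     min_mapped = 0.8) {
  loci <- dataset$loci
  d <- dosage(dataset)
  acc <- dataset$samples$accession_id

  per_contig <- loci |>
    mutate(idx = dplyr::row_number()) |>
    group_by(.data$gene, .data$subgenome, .data$contig_id) |>
    summarise(idx = list(.data$idx), n_snp = n(), .groups = "drop")

  mapped_frac <- map_dbl(per_contig$idx, function(ix) {
    called <- !is.na(d[, ix, drop = FALSE])
    mean(tapply(rowMeans(called) > 0, acc, any))
  })
  per_contig$mapped_frac <- mapped_frac

  genes <- per_contig |>
    filter(.data$subgenome %in% c("K", "N"),
           .data$mapped_frac > min_mapped) |>
    group_by(.data$gene) |>
    filter(dplyr::n_distinct(.data$subgenome) == 2) |>
    ungroup()

  purrr::map_dfr(unique(genes$gene), function(g) {
    gk <- filter(genes, .data$gene == g, .data$subgenome == "K")
    gn <- filter(genes, .data$gene == g, .data$subgenome == "N")
    nk <- sum(gk$n_snp); nn <- sum(gn$n_snp)
    if (!is.null(contig_lengths)) {
      lk <- sum(contig_lengths[gk$contig_id])
      ln <- sum(contig_lengths[gn$contig_id])
      pk <- 100 * nk / lk; pn <- 100 * nn / ln
    } else {
      tot <- nk + nn
      pk <- if (tot) 100 * nk / tot else 0
      pn <- if (tot) 100 * nn / tot else 0
    }
    tibble(gene = g, pctP_K = pk, pctP_N = pn, delta = pk - pn,
           n_snp_K = nk, n_snp_N = nn,
           shared_region_only = !is.null(contig_lengths))
  })
}
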