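#' Per-locus diversity indices
#'
#' Classical codominant per-locus indices computed from called genotypes:
#' expected heterozygosity `He = 1 - sum(p^2)`, effective allele number
#' `Ne = 1 / sum(p^2)`, Shannon information `I = -sum(p log p)` (nats),
#' observed heterozygosity `Ho` (fraction of heterozygous calls), and
#' fixation index `F = 1 - Ho / He` (0 where `He = 0`).
#'
#' @param dataset A filtered [snp_dataset()].
#' @param by Optional per-sample group labels; indices are then computed
#'   within each group.
#' @return Tibble with one row per locus (x group), columns `Ne`, `I`, `Ho`,
#'   `He`, `Fis`, `is_polymorphic`, `n_called`.
#' @export
locus_diversity <- function(dataset, by = NULL) {
  stopifnot(inherits(dataset, "snp_dataset"))
  d <- dosage(dataset)
  if (any(colSums(!is.na(d)) == 0) && is.null(by)) {
    abort("locus with no non-missing calls")
  }
  groups <- if (is.null(by)) list(`.all` = seq_len(nrow(d)))
            else split(seq_len(nrow(d)), by)
  out <- purrr::map_dfr(groups, function(idx) {
    purrr::map_dfr(seq_len(ncol(d)), function(j) {
      p <- locus_allele_freqs(dataset, j, idx)
      p <- p[!is.na(p) & p > 0]
      states <- dataset$state[idx, j]
      called <- states %in% c("hom_ref", "het", "hom_alt")
      if (!length(p) || !any(called)) {
        return(tibble(locus_id = colnames(d)[j], Ne = NA_real_, I = NA_real_,
                      Ho = NA_real_, He = NA_real_, Fis = NA_real_,
                      is_polymorphic = NA, n_called = 0L))
      }
      he <- 1 - sum(p^2)
      ho <- mean(states[called] == "het")
      tibble(
        locus_id = colnames(d)[j],
        Ne = 1 / sum(p^2),
        I = -sum(p * log(p)),
        Ho = ho,
        He = he,
        Fis = if (he > 0) 1 - ho / he else 0,
        is_polymorphic = he > 0,
        n_called = sum(called)
      )
    })
  }, .id = "group")
  if (is.null(by)) out$group <- NULL
  out
}

#' Group diversity summary (panel or subpopulation level)
#'
#' Per-group sample size, number of polymorphic loci, private-allele count,
#' percentage of polymorphic loci, and mean with standard error over loci of
#' Ne, I, Ho, He, F.
#'
#' @param dataset A filtered [snp_dataset()].
#' @param by Per-sample group labels (e.g. inferred subpopulation).
#' @return Tibble with one row per group.
#' @export
diversity_summary <- function(dataset, by) {
  stopifnot(length(by) == nrow(dataset$samples))
  ld <- locus_diversity(dataset, by = by)
  groups <- unique(by)

  # allele presence per group for private-allele counting
  pres <- purrr::map(setNames(groups, groups), function(g) {
    idx <- which(by == g)
    purrr::map(seq_len(nrow(dataset$loci)), function(j) {
      p <- locus_allele_freqs(dataset, j, idx)
      names(p)[!is.na(p) & p > 0]
    })
  })
  private_count <- purrr::map_int(setNames(groups, groups), function(g) {
    others <- setdiff(groups, g)
    sum(purrr::map_int(seq_len(nrow(dataset$loci)), function(j) {
      mine <- pres[[g]][[j]]
      theirs <- unique(unlist(purrr::map(others, function(o) pres[[o]][[j]])))
      length(setdiff(mine, theirs))
    }))
  })

  se <- function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  ld |>
    group_by(.data$group) |>
    summarise(
      N = length(unique(dataset$samples$sample_id[by == .data$group[1]])),
      Np = sum(.data$is_polymorphic, na.rm = TRUE),
      pctP = 100 * mean(.data$is_polymorphic, na.rm = TRUE),
      Ne_se = se(.data$Ne), Ne = mean(.data$Ne, na.rm = TRUE),
      I_se = se(.data$I), I = mean(.data$I, na.rm = TRUE),
      Ho_se = se(.data$Ho), Ho = mean(.data$Ho, na.rm = TRUE),
      He_se = se(.data$He), He = mean(.data$He, na.rm = TRUE),
      Fis_se = se(.data$Fis), Fis = mean(.data$Fis, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(private_alleles = unname(private_count[.data$group])) |>
    select("group", "N", "Np", "private_alleles", "pctP",
           dplyr::everything())
}
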