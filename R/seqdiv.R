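harmonic <- function(n, power = 1) sum(1 / seq_len(n)^power)

#' Tajima's D from summary quantities
#'
#' `D = (pi * L - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))` with the
#' standard constants `a1, a2, b1, b2, c1, c2, e1, e2` of the neutral-theory
#' test.
#'
#' @param pi_site Nucleotide diversity per site.
#' @param S Number of segregating sites.
#' @param n Number of sequences (2 x samples for phased diploid data).
#' @param L Alignment length in bp.
#' @return Tajima's D (NA when `S = 0`).
#' @export
tajima_d <- function(pi_site, S, n, L) {
  if (S == 0) return(NA_real_)
  if (n < 4) abort("Tajima's D needs at least 4 sequences")
  a1 <- harmonic(n - 1); a2 <- harmonic(n - 1, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_site * L - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

fu_li_constants <- function(n, variant = c("F", "Fstar")) {
  variant <- match.arg(variant)
  an <- harmonic(n - 1); bn <- harmonic(n - 1, 2)
  an1 <- an + 1 / n
  if (variant == "F") {
    cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
    vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
      (an^2 + bn)
    uF <- (1 + (n + 1) / (3 * (n - 1)) -
             4 * ((n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  } else {
    vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
             2 * (n - 1) * an / n^2 - 8 * bn / n) / (an^2 + bn)
    uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
             2 * ((n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  }
  list(u = uF, v = vF)
}

#' Fu & Li's F (with outgroup) or F* (without)
#'
#' Contrasts the mean pairwise difference with the singleton count. With an
#' outgroup allele per segregating site the statistic uses external-branch
#' (derived) singletons (`F`); without one it falls back on sample
#' singletons (`F*`). The variant actually used is recorded on the result.
#'
#' @param haps 2n x S matrix of 0/1 (or small-integer) alleles, one row per
#'   phased sequence.
#' @param outgroup Optional length-S vector of outgroup allele codes on the
#'   same coding as `haps`; any `NA` entry forces the `F*` variant.
#' @return Numeric value with attribute `variant` (`"F"` or `"Fstar"`); NA
#'   when no site segregates.
#' @export
fu_li_f <- function(haps, outgroup = NULL) {
  haps <- as.matrix(haps)
  n <- nrow(haps)
  if (n < 4) abort("Fu & Li's F needs at least 4 sequences")
  seg <- which(apply(haps, 2, function(x) length(unique(x)) > 1))
  S <- length(seg)
  if (S == 0) return(structure(NA_real_, variant = "none"))

  k_hat <- 0  # mean pairwise differences (absolute)
  for (j in seg) {
    tab <- table(haps[, j])
    p <- as.numeric(tab) / n
    k_hat <- k_hat + (n / (n - 1)) * (1 - sum(p^2))
  }

  use_F <- !is.null(outgroup) && !anyNA(outgroup[seg])
  if (use_F) {
    eta_e <- sum(purrr::map_int(seg, function(j) {
      tab <- table(haps[, j])
      derived <- setdiff(names(tab), as.character(outgroup[j]))
      sum(as.integer(tab[derived]) == 1L)
    }))
    cst <- fu_li_constants(n, "F")
    num <- k_hat - eta_e
  } else {
    eta_s <- sum(purrr::map_int(seg, function(j) {
      tab <- table(haps[, j])
      sum(as.integer(tab) == 1L)
    }))
    cst <- fu_li_constants(n, "Fstar")
    num <- k_hat - ((n - 1) / n) * eta_s
  }
  val <- num / sqrt(cst$u * S + cst$v * S^2)
  structure(val, variant = if (use_F) "F" else "Fstar")
}

#' Per-contig sequence diversity from phased haplotypes
#'
#' Nucleotide diversity per site (heterozygosity form with the `n/(n-1)`
#' bias factor), Watterson's theta per site, their standard deviations from
#' the standard neutral-theory variance formulas, haplotype count and
#' diversity, SNP density `d = 100 * S / L`, Tajima's D and Fu & Li's F.
#'
#' @param haps 2n x S haplotype matrix ([haplotype_matrix()]) or a
#'   `pvp_haplotypes` object.
#' @param L Alignment length of the contig in bp.
#' @param outgroup Optional outgroup allele vector passed to [fu_li_f()].
#' @return One-row tibble (class-tagged `pvp_seqdiv` columns).
#' @export
sequence_diversity <- function(haps, L, outgroup = NULL) {
  if (inherits(haps, "pvp_haplotypes")) haps <- haplotype_matrix(haps)
  haps <- as.matrix(haps)
  n <- nrow(haps)
  if (n < 2) abort("need at least 2 phased sequences")
  if (L <= 0) abort("alignment length must be positive")

  seg <- which(apply(haps, 2, function(x) length(unique(x[!is.na(x)])) > 1))
  S <- length(seg)
  pi_sum <- 0
  for (j in seg) {
    x <- haps[, j]; x <- x[!is.na(x)]; ns <- length(x)
    p <- as.numeric(table(x)) / ns
    pi_sum <- pi_sum + (ns / (ns - 1)) * (1 - sum(p^2))
  }
  pi_site <- pi_sum / L

  a1 <- harmonic(n - 1); a2 <- harmonic(n - 1, 2)
  theta_site <- S / (a1 * L)
  var_theta <- theta_site / (a1 * L) + (a2 / a1^2) * theta_site^2
  var_pi <- (n + 1) / (3 * (n - 1)) * pi_site / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi_site^2

  key <- apply(haps, 1, paste, collapse = "")
  f <- as.numeric(table(key)) / n
  h <- length(f)
  hd <- if (n > 1) (n / (n - 1)) * (1 - sum(f^2)) else 0
  s2 <- sum(f^2)
  var_hd <- max(0, 2 / (n * (n - 1)) *
                  (2 * (n - 2) * (sum(f^3) - s2^2) + s2 - s2^2))

  flf <- if (S > 0 && n >= 4) fu_li_f(haps, outgroup)
         else structure(NA_real_, variant = "none")

  tibble(
    n_seq = n, L = L, S_tot = S,
    pi = pi_site, sd_pi = sqrt(max(var_pi, 0)),
    theta_w = theta_site, sd_theta = sqrt(max(var_theta, 0)),
    h = h, Hd = hd, sd_Hd = sqrt(var_hd),
    snp_density_d = 100 * S / L,
    tajima_D = if (S > 0 && n >= 4) tajima_d(pi_site, S, n, L) else NA_real_,
    fu_li_F = as.numeric(flf),
    fu_li_variant = attr(flf, "variant")
  )
}

#' SNP density as printed in per-gene summary tables
#'
#' @param S Segregating-site count.
#' @param L Alignment length (bp).
#' @return Percent polymorphism `100 * S / L`.
#' @export
snp_density <- function(S, L) 100 * S / L
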