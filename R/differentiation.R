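group_alt_freqs <- function(d, groups) {
  # d: dosage matrix; returns G x L matrix of alt frequencies
  do.call(rbind, lapply(split(seq_len(nrow(d)), groups), function(idx) {
    colMeans(d[idx, , drop = FALSE], na.rm = TRUE)
  }))
}

gst_from_freqs <- function(pf) {
  # pf: G x L alt-frequency matrix (NaN where a group has no calls)
  hs <- colMeans(2 * pf * (1 - pf), na.rm = TRUE)
  pbar <- colMeans(pf, na.rm = TRUE)
  ht <- 2 * pbar * (1 - pbar)
  keep <- !is.na(ht)
  Hs <- mean(hs[keep]); Ht <- mean(ht[keep])
  if (!is.finite(Ht) || Ht == 0) return(NA_real_)
  (Ht - Hs) / Ht
}

#' Overall Gst with permutation significance
#'
#' Nei's coefficient of gene differentiation over loci:
#' `Gst = (Ht - Hs) / Ht` with `Ht` the expected heterozygosity of the
#' pooled (mean) allele frequencies and `Hs` the mean within-group expected
#' heterozygosity, both averaged over loci before taking the ratio.
#' Significance from permuting individuals across groups.
#'
#' @param dataset A filtered [snp_dataset()].
#' @param groups Per-sample group labels (at least two groups).
#' @param n_perm Number of permutations (default 999).
#' @return Object of class `pvp_gst`: list with `gst`, `p`, `n_perm`.
#' @export
gst_overall <- function(dataset, groups, n_perm = 999) {
  stopifnot(inherits(dataset, "snp_dataset"))
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) abort("need at least two groups")
  d <- dosage(dataset)
  obs <- gst_from_freqs(group_alt_freqs(d, groups))
  if (is.na(obs)) abort("Gst undefined: all loci monomorphic")
  perm <- map_dbl(seq_len(n_perm), function(i) {
    gst_from_freqs(group_alt_freqs(d, sample(groups)))
  })
  p <- (1 + sum(perm >= obs, na.rm = TRUE)) / (n_perm + 1)
  structure(list(gst = obs, p = p, n_perm = n_perm), class = "pvp_gst")
}

#' @export
print.pvp_gst <- function(x, ...) {
  cat(sprintf("<pvp_gst> Gst = %.3f, P = %.3g (%d permutations)\n",
              x$gst, x$p, x$n_perm))
  invisible(x)
}

#' Pairwise Fst and Nei's standard genetic distance
#'
#' Fst for each pair of groups is Nei's Gst restricted to the pair
#' (a Weir-Cockerham estimator is available as an option); Nei's standard
#' distance is `D = -ln(Jxy / sqrt(Jx * Jy))` with the gene identities
#' averaged over loci. Pairs with no shared alleles anywhere yield an
#' infinite D, capped at `cap` and flagged.
#'
#' @param dataset A filtered [snp_dataset()].
#' @param groups Per-sample group labels; each group needs >= 2 individuals.
#' @param estimator `"nei"` (default) or `"wc"` for Weir-Cockerham theta.
#' @param cap Ceiling for infinite Nei distances (default 10).
#' @return List with symmetric matrices `fst` and `nei` (group labels as
#'   dimnames) and `nei_capped` flag matrix.
#' @export
pairwise_differentiation <- function(dataset, groups,
                                     estimator = c("nei", "wc"), cap = 10) {
  estimator <- match.arg(estimator)
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab < 2)) abort("each group needs at least two individuals")
  gs <- names(tab)
  d <- dosage(dataset)
  pf <- group_alt_freqs(d, groups)

  G <- length(gs)
  fst <- matrix(0, G, G, dimnames = list(gs, gs))
  nei <- matrix(0, G, G, dimnames = list(gs, gs))
  capped <- matrix(FALSE, G, G, dimnames = list(gs, gs))
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    pi_ <- pf[gs[i], ]; pj <- pf[gs[j], ]
    fst[i, j] <- fst[j, i] <- if (estimator == "nei") {
      gst_from_freqs(rbind(pi_, pj))
    } else {
      wc_theta_pair(d[groups == gs[i], , drop = FALSE],
                    d[groups == gs[j], , drop = FALSE])
    }
    keep <- !is.na(pi_) & !is.na(pj)
    jx <- mean(pi_[keep]^2 + (1 - pi_[keep])^2)
    jy <- mean(pj[keep]^2 + (1 - pj[keep])^2)
    jxy <- mean(pi_[keep] * pj[keep] + (1 - pi_[keep]) * (1 - pj[keep]))
    D <- if (jxy <= 0) Inf else -log(jxy / sqrt(jx * jy))
    if (!is.finite(D) || D > cap) { D <- cap; capped[i, j] <- capped[j, i] <- TRUE }
    nei[i, j] <- nei[j, i] <- max(D, 0)
  }
  list(fst = fst, nei = nei, nei_capped = capped)
}

wc_theta_pair <- function(d1, d2) {
  # Weir & Cockerham (1984) theta for two populations, biallelic dosages
  num <- 0; den <- 0
  for (j in seq_len(ncol(d1))) {
    x1 <- d1[, j]; x2 <- d2[, j]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) next
    p1 <- mean(x1); p2 <- mean(x2)
    h1 <- mean(x1 == 0.5); h2 <- mean(x2 == 0.5)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a; den <- den + a + b + cc
  }
  if (den == 0) NA_real_ else num / den
}

#' Gene flow from Gst
#'
#' `Nm = 0.5 * (1 - Gst) / Gst`, the classical island-model translation of
#' differentiation into effective migrants per generation.
#'
#' @param gst Gst value(s) in `(0, 1]`.
#' @return Numeric vector; `Inf` (with a warning) where `gst <= 0`.
#' @export
gene_flow_nm <- function(gst) {
  out <- ifelse(gst > 0, 0.5 * (1 - gst) / gst, Inf)
  if (any(!is.na(gst) & gst <= 0)) warn("gst <= 0: gene flow reported as Inf")
  out
}
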