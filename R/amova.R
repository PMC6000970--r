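gamete_matrix <- function(d) {
  # expand a samples x loci dosage matrix into a 2N x L allele (0/1) matrix;
  # the het split (0 then 1) is arbitrary but consistent - between-individual
  # distances are unaffected and within-individual distances are exact
  n <- nrow(d); L <- ncol(d)
  X <- matrix(NA_real_, 2 * n, L)
  g1 <- d; g1[d == 0.5] <- 0
  g2 <- d; g2[d == 0.5] <- 1
  X[seq(1, 2 * n, by = 2), ] <- g1
  X[seq(2, 2 * n, by = 2), ] <- g2
  rownames(X) <- paste0(rep(rownames(d) %||% seq_len(n), each = 2), c("_a", "_b"))
  X
}

gamete_sqdist <- function(X) {
  # squared Euclidean distance with pairwise-complete loci, rescaled to the
  # full locus count
  L <- ncol(X)
  M <- (!is.na(X)) * 1
  X0 <- X; X0[is.na(X0)] <- 0
  A <- X0^2
  shared <- M %*% t(M)
  D2 <- A %*% t(M) + M %*% t(A) - 2 * X0 %*% t(X0)
  scale <- ifelse(shared > 0, L / shared, 0)
  D2 <- D2 * scale
  diag(D2) <- 0
  D2
}

amova_ss <- function(D2, ind_of, grp_of_ind) {
  # D2: 2N x 2N squared distances among gametes; ind_of: individual index per
  # gamete; grp_of_ind: group label per individual
  n_tot <- nrow(D2)
  grp_of <- grp_of_ind[ind_of]
  ss_tot <- sum(D2) / (2 * n_tot)
  E_g <- stats::model.matrix(~ 0 + factor(grp_of))
  within_g <- diag(t(E_g) %*% D2 %*% E_g) / 2
  n_g <- colSums(E_g)
  ss_wg <- sum(within_g / n_g)
  E_i <- stats::model.matrix(~ 0 + factor(ind_of))
  within_i <- diag(t(E_i) %*% D2 %*% E_i) / 2
  ss_wi <- sum(within_i / 2)
  list(ss_ag = ss_tot - ss_wg, ss_ai = ss_wg - ss_wi, ss_wi = ss_wi,
       ss_tot = ss_tot)
}

amova_components <- function(ss, N, G, group_sizes) {
  # nested random-effects coefficients; gametes per individual is always 2
  n <- 2 * N
  df_ag <- G - 1; df_ai <- N - G; df_wi <- N
  ms_ag <- ss$ss_ag / df_ag
  ms_ai <- if (df_ai > 0) ss$ss_ai / df_ai else 0
  ms_wi <- ss$ss_wi / df_wi
  n1 <- 2                                        # coef of sigma2_AI in MS_AI
  n2 <- 2                                        # coef of sigma2_AI in MS_AG
  n3 <- (n - sum((2 * group_sizes)^2) / n) / df_ag  # coef of sigma2_AG
  s_wi <- ms_wi
  s_ai <- max((ms_ai - s_wi) / n1, 0)
  s_ag <- max((ms_ag - s_wi - n2 * s_ai) / n3, 0)
  list(df = c(df_ag, df_ai, df_wi), ms = c(ms_ag, ms_ai, ms_wi),
       est_var = c(s_ag, s_ai, s_wi))
}

#' Three-level codominant AMOVA with permutation tests
#'
#' Hierarchical partition of molecular variance among groups, among
#' individuals within groups, and within individuals, computed from squared
#' Euclidean distances between allele-level (gametic) dosage vectors - the
#' codominant-genotypic convention. Missing loci are excluded pairwise and
#' the squared distance rescaled to the full locus count. Variance
#' components are estimated from the nested mean squares and truncated at
#' zero. Permutation p-values: the among-group component permutes whole
#' individuals among groups; Phi_IS permutes gametes among individuals
#' within groups.
#'
#' @param dataset A filtered [snp_dataset()] (or a dosage matrix).
#' @param groups Per-sample group labels (subpopulation, accession,
#'   latitude bin, ...). Groups of size 1 are merged into a shared residual
#'   group with a warning.
#' @param n_perm Number of permutations (default 999).
#' @return Object of class `pvp_amova`: `levels` tibble (label, df, SS, MS,
#'   est_var, pct), `phi` tibble, `p_values` tibble, `n_perm`.
#' @export
amova <- function(dataset, groups, n_perm = 999) {
  d <- if (inherits(dataset, "snp_dataset")) dosage(dataset) else as.matrix(dataset)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  tab <- table(groups)
  if (any(tab == 1)) {
    warn(sprintf("%d group(s) of size 1 merged into a residual group",
                 sum(tab == 1)))
    groups[groups %in% names(tab)[tab == 1]] <- "_residual"
  }
  if (length(unique(groups)) < 2) abort("need at least two groups of size > 1")

  N <- nrow(d)
  X <- gamete_matrix(d)
  D2 <- gamete_sqdist(X)
  ind_of <- rep(seq_len(N), each = 2)

  compute <- function(grp_of_ind) {
    ss <- amova_ss(D2, ind_of, grp_of_ind)
    sizes <- table(grp_of_ind)
    comp <- amova_components(ss, N, length(sizes), as.numeric(sizes))
    comp$ss <- c(ss$ss_ag, ss$ss_ai, ss$ss_wi)
    comp
  }
  obs <- compute(groups)
  tot_var <- sum(obs$est_var)
  pct <- if (tot_var > 0) 100 * obs$est_var / tot_var else c(0, 0, 100)
  phi_ct <- if (tot_var > 0) obs$est_var[1] / tot_var else 0
  phi_is <- if (sum(obs$est_var[2:3]) > 0)
    obs$est_var[2] / sum(obs$est_var[2:3]) else 0
  phi_it <- if (tot_var > 0) sum(obs$est_var[1:2]) / tot_var else 0

  # among-group test: permute individuals among groups
  perm_ag <- map_dbl(seq_len(n_perm), function(i) {
    cp <- compute(sample(groups))
    tv <- sum(cp$est_var)
    if (tv > 0) cp$est_var[1] / tv else 0
  })
  p_ag <- (1 + sum(perm_ag >= phi_ct)) / (n_perm + 1)

  # within-group test: permute gametes among individuals within groups
  perm_is <- map_dbl(seq_len(n_perm), function(i) {
    new_ind <- ind_of
    for (g in unique(groups)) {
      rows <- which(groups[ind_of] == g)
      new_ind[rows] <- sample(ind_of[rows])
    }
    ss <- amova_ss(D2, new_ind, groups)
    sizes <- table(groups)
    cp <- amova_components(ss, N, length(sizes), as.numeric(sizes))
    if (sum(cp$est_var[2:3]) > 0) cp$est_var[2] / sum(cp$est_var[2:3]) else 0
  })
  p_is <- (1 + sum(perm_is >= phi_is)) / (n_perm + 1)

  levels <- tibble(
    label = c("Among groups", "Among individuals", "Within individuals",
              "Total"),
    df = c(obs$df, sum(obs$df)),
    SS = c(obs$ss, sum(obs$ss)),
    MS = c(obs$ms, NA_real_),
    est_var = c(obs$est_var, tot_var),
    pct = c(pct, 100)
  )
  structure(
    list(levels = levels,
         phi = tibble(statistic = c("Phi_CT", "Phi_IS", "Phi_IT"),
                      value = c(phi_ct, phi_is, phi_it)),
         p_values = tibble(test = c("among_groups", "among_individuals"),
                           p = c(p_ag, p_is)),
         n_perm = n_perm),
    class = "pvp_amova"
  )
}

#' @export
print.pvp_amova <- function(x, ...) {
  cat("<pvp_amova>\n")
  print(as.data.frame(x$levels), row.names = FALSE, digits = 4)
  cat(sprintf("P(among groups) = %.3g, P(among individuals) = %.3g [%d perms]\n",
              x$p_values$p[1], x$p_values$p[2], x$n_perm))
  invisible(x)
}

#' AMOVA percentage column from printed variance components
#'
#' Reporting arithmetic used in the standard AMOVA table layout: each
#' estimated variance component as an integer-rounded percentage of their
#' sum.
#'
#' @param est_var Numeric vector of variance components.
#' @return Integer percentages.
#' @export
amova_percentages <- function(est_var) {
  round(100 * est_var / sum(est_var))
}
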