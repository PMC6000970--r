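#' Haplotype phasing by Excoffier-Slatkin EM
#'
#' Maximum-likelihood haplotype frequency estimation for the SNPs of one
#' amplicon contig, with each multi-site heterozygote resolved to its most
#' probable haplotype pair under the fitted frequencies. At amplicon scale
#' (tens of SNPs, few heterozygous sites per individual) the EM algorithm is
#' an adequate, deterministic alternative to coalescent-informed Gibbs
#' phasing; the solver enumerates all haplotype pairs compatible with each
#' genotype, so the number of heterozygous sites per individual is capped.
#'
#' Missing genotypes are imputed to the locus major-allele homozygote before
#' phasing (the imputed count is reported), so every sample contributes
#' exactly two haplotypes.
#'
#' @param geno Samples x sites matrix of alt dosages (0, 0.5, 1, `NA`), e.g.
#'   a contig slice of [dosage()].
#' @param n_restarts Random restarts in addition to the uniform start.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param max_het Maximum heterozygous sites per individual (enumeration is
#'   `2^(h-1)` pairs).
#' @return Object of class `pvp_haplotypes`: list with `haplotypes` (tibble:
#'   sample_id, hap1, hap2, best pair posterior), `frequencies` (tibble:
#'   haplotype, freq), `log_likelihood`, `converged`, `n_imputed`.
#' @export
phase_haplotypes <- function(geno, n_restarts = 3, max_iter = 500,
                             tol = 1e-6, max_het = 16) {
  geno <- as.matrix(geno)
  n <- nrow(geno); S <- ncol(geno)
  if (n < 1 || S < 1) abort("empty genotype matrix")
  ids <- rownames(geno) %||% paste0("s", seq_len(n))
  g <- round(2 * geno)  # 0 / 1 / 2 alt copies

  n_imputed <- sum(is.na(g))
  if (n_imputed > 0) {
    for (j in seq_len(S)) {
      fr <- mean(g[, j], na.rm = TRUE) / 2
      if (is.nan(fr)) fr <- 0
      g[is.na(g[, j]), j] <- if (fr > 0.5) 2 else 0
    }
  }

  het_counts <- rowSums(g == 1)
  if (any(het_counts > max_het)) {
    abort(sprintf("individual with %d heterozygous sites exceeds max_het = %d",
                  max(het_counts), max_het))
  }

  hap_key <- function(h) paste(h, collapse = "")
  # compatible (unordered) haplotype pairs per sample
  pairs <- map(seq_len(n), function(i) {
    gi <- g[i, ]
    het <- which(gi == 1)
    base <- ifelse(gi == 2, 1L, 0L)
    if (length(het) == 0) {
      return(list(a = hap_key(base), b = hap_key(base)))
    }
    k <- length(het)
    # fix the first het site on haplotype A to enumerate unordered pairs
    combos <- if (k == 1) matrix(1L, 1, 1) else
      cbind(1L, as.matrix(expand.grid(rep(list(0:1), k - 1))))
    a_list <- character(nrow(combos)); b_list <- character(nrow(combos))
    for (r in seq_len(nrow(combos))) {
      ha <- base; hb <- base
      ha[het] <- combos[r, ]; hb[het] <- 1L - combos[r, ]
      a_list[r] <- hap_key(ha); b_list[r] <- hap_key(hb)
    }
    list(a = a_list, b = b_list)
  })

  all_haps <- unique(unlist(map(pairs, function(p) c(p$a, p$b))))
  H <- length(all_haps)
  hap_idx <- setNames(seq_len(H), all_haps)
  pairs_i <- map(pairs, function(p)
    cbind(a = hap_idx[p$a], b = hap_idx[p$b]))

  run_em <- function(f0) {
    f <- f0
    ll_old <- -Inf; converged <- FALSE
    for (it in seq_len(max_iter)) {
      counts <- numeric(H); ll <- 0
      for (i in seq_len(n)) {
        pr <- pairs_i[[i]]
        w <- f[pr[, "a"]] * f[pr[, "b"]] * ifelse(pr[, "a"] == pr[, "b"], 1, 2)
        tw <- sum(w)
        if (tw <= 0) { w <- rep(1 / nrow(pr), nrow(pr)); tw <- 1e-300 }
        ll <- ll + log(tw)
        w <- w / sum(w)
        for (r in seq_len(nrow(pr))) {
          counts[pr[r, "a"]] <- counts[pr[r, "a"]] + w[r]
          counts[pr[r, "b"]] <- counts[pr[r, "b"]] + w[r]
        }
      }
      f <- counts / (2 * n)
      if (ll - ll_old < tol && it > 1) { converged <- TRUE; break }
      ll_old <- ll
    }
    list(f = f, ll = ll, converged = converged)
  }

  starts <- c(list(rep(1 / H, H)),
              map(seq_len(n_restarts), function(r) {
                x <- rgamma(H, 1); x / sum(x)
              }))
  fits <- map(starts, run_em)
  best <- fits[[which.max(map_dbl(fits, "ll"))]]
  if (!best$converged) {
    warn("EM did not converge within max_iter; returning best solution")
  }

  calls <- purrr::map_dfr(seq_len(n), function(i) {
    pr <- pairs_i[[i]]
    w <- best$f[pr[, "a"]] * best$f[pr[, "b"]] *
      ifelse(pr[, "a"] == pr[, "b"], 1, 2)
    r <- if (all(w == 0)) 1L else which.max(w)
    tibble(sample_id = ids[i],
           hap1 = all_haps[pr[r, "a"]], hap2 = all_haps[pr[r, "b"]],
           pair_posterior = if (sum(w) > 0) w[r] / sum(w) else NA_real_)
  })

  structure(
    list(
      haplotypes = calls,
      frequencies = tibble(haplotype = all_haps, freq = best$f) |>
        filter(.data$freq > 1e-9) |> arrange(dplyr::desc(.data$freq)),
      log_likelihood = best$ll,
      converged = best$converged,
      n_imputed = n_imputed
    ),
    class = "pvp_haplotypes"
  )
}

#' @export
print.pvp_haplotypes <- function(x, ...) {
  cat(sprintf("<pvp_haplotypes> %d samples, %d haplotypes, logLik %.3f%s\n",
              nrow(x$haplotypes), nrow(x$frequencies), x$log_likelihood,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Phased haplotypes as a 2n x S allele matrix
#'
#' @param x A `pvp_haplotypes` object.
#' @return Integer matrix (two rows per sample) of 0/1 alleles.
#' @export
haplotype_matrix <- function(x) {
  stopifnot(inherits(x, "pvp_haplotypes"))
  split1 <- function(s) as.integer(strsplit(s, "")[[1]])
  m <- do.call(rbind, c(map(x$haplotypes$hap1, split1),
                        map(x$haplotypes$hap2, split1)))
  ord <- as.vector(rbind(seq_len(nrow(x$haplotypes)),
                         nrow(x$haplotypes) + seq_len(nrow(x$haplotypes))))
  m <- m[ord, , drop = FALSE]
  rownames(m) <- paste0(rep(x$haplotypes$sample_id, each = 2), c("_a", "_b"))
  m
}
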