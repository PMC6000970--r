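# Shared fixtures and independent oracles. Everything here is deliberately
# coded from first principles (closed forms, enumeration, simulation) and
# never calls the package functions it is used to check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal dataset builders ----------------------------------------------

toy_samples <- function(n, ecotype = NULL, lat = NULL, lon = NULL,
                        accession = NULL) {
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    accession_id = accession %||% rep("accA", n),
    ecotype = ecotype %||% rep("unknown", n),
    ploidy = "4x",
    latitude = lat %||% runif(n, 30, 45),
    longitude = lon %||% runif(n, -100, -80)
  )
}

toy_loci <- function(L, contig = "ctg1", positions = NULL, ref = "G",
                     alt = "A", region = "intron", outgroup = NA) {
  tibble::tibble(
    locus_id = sprintf("%s_p%04d", contig, positions %||% (seq_len(L) * 10)),
    contig_id = contig, gene = "geneX", chromosome = "Chr01K",
    subgenome = "K", position = positions %||% (seq_len(L) * 10),
    ref_allele = rep_len(ref, L), alt_alleles = rep_len(alt, L),
    region = rep_len(region, L), codon_frame = NA_integer_,
    outgroup_allele = rep_len(outgroup, L)
  )
}

# dataset whose alt fractions equal the requested dosages exactly
ds_from_dosage <- function(d, depth = 100L, ...) {
  d <- as.matrix(d)
  n <- nrow(d); L <- ncol(d)
  dep <- matrix(depth, n, L)
  af <- d
  dep[is.na(d)] <- 0L
  snp_dataset(toy_samples(n, ...), toy_loci(L), dep, af)
}

# ---- Hudson coalescent with infinite-sites mutations ------------------------
# Independent neutral-model oracle: exponential coalescent intervals, Poisson
# mutations (rate theta/2 per unit branch length) dropped on active lineages.

sim_coalescent <- function(n, theta) {
  lineages <- lapply(seq_len(n), identity)  # descendant leaf sets
  muts <- list()  # each element: leaf set carrying the derived allele
  k <- n
  while (k > 1) {
    t_k <- rexp(1, rate = k * (k - 1) / 2)
    n_mut <- rpois(1, theta / 2 * t_k * k)
    if (n_mut > 0) {
      hit <- sample.int(k, n_mut, replace = TRUE)
      for (h in hit) muts[[length(muts) + 1]] <- lineages[[h]]
    }
    pair <- sample.int(k, 2)
    lineages[[pair[1]]] <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    lineages[[pair[2]]] <- NULL
    k <- k - 1
  }
  S <- length(muts)
  haps <- matrix(0L, n, max(S, 1))
  for (j in seq_len(S)) haps[muts[[j]], j] <- 1L
  if (S == 0) haps <- haps[, 0, drop = FALSE]
  haps
}

# ---- independent neutrality-test constants ----------------------------------
# Recomputed from the published formulas, separately from the package code.

oracle_tajima_d <- function(k_hat, S, n) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

mean_pairwise_diff <- function(haps) {
  n <- nrow(haps)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(haps[i, ] != haps[j, ])
  }
  tot / (n * (n - 1) / 2)
}

# ---- exhaustive-likelihood oracle for two-site phasing ----------------------
# Grid search over haplotype frequencies (00, 01, 10, 11) maximizing the
# multinomial likelihood of the 3x3 genotype table under Hardy-Weinberg.

phase_grid_oracle <- function(geno, step = 0.02) {
  counts <- table(factor(geno[, 1], levels = c(0, 0.5, 1)),
                  factor(geno[, 2], levels = c(0, 0.5, 1)))
  gprob <- function(f) {
    # f = c(f00, f01, f10, f11); genotype class probabilities
    p <- matrix(0, 3, 3)
    hap <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
    for (a in 1:4) for (b in 1:4) {
      g1 <- (hap[a, 1] + hap[b, 1]) / 2
      g2 <- (hap[a, 2] + hap[b, 2]) / 2
      i <- match(g1, c(0, 0.5, 1)); j <- match(g2, c(0, 0.5, 1))
      p[i, j] <- p[i, j] + f[a] * f[b]
    }
    p
  }
  best <- NULL; best_ll <- -Inf
  grid <- seq(0, 1, by = step)
  for (f1 in grid) for (f2 in grid) for (f3 in grid) {
    f4 <- 1 - f1 - f2 - f3
    if (f4 < -1e-9) next
    f4 <- max(f4, 0)
    p <- gprob(c(f1, f2, f3, f4))
    ll <- sum(counts * log(pmax(p, 1e-12)))
    if (ll > best_ll) { best_ll <- ll; best <- c(f1, f2, f3, f4) }
  }
  names(best) <- c("00", "01", "10", "11")
  list(freqs = best, loglik = best_ll)
}

# ---- Balding-Nichols panel ---------------------------------------------------

sim_bn_panel <- function(n_per_pop, n_loci, F, n_pops = 2) {
  p0 <- runif(n_loci, 0.05, 0.95)
  pk <- sapply(p0, function(q)
    if (F > 0) rbeta(n_pops, q * (1 - F) / F, (1 - q) * (1 - F) / F)
    else rep(q, n_pops))
  if (n_pops == 1) pk <- matrix(pk, nrow = 1)
  d <- do.call(rbind, lapply(seq_len(n_pops), function(k) {
    matrix(rbinom(n_per_pop * n_loci, 2,
                  rep(pk[k, ], each = n_per_pop)) / 2, n_per_pop, n_loci)
  }))
  list(dosage = d, true_freqs = pk,
       pop = rep(paste0("P", seq_len(n_pops)), each = n_per_pop))
}

# Nei Gst computed directly from a set of allele-frequency vectors (oracle
# shared closed form, used both on true and on estimated frequencies)
oracle_gst <- function(pf) {
  hs <- colMeans(2 * pf * (1 - pf))
  pbar <- colMeans(pf)
  ht <- 2 * pbar * (1 - pbar)
  (mean(ht) - mean(hs)) / mean(ht)
}
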