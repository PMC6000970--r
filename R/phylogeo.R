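#' Great-circle geographic distance matrix
#'
#' Haversine distances in km from decimal-degree coordinates.
#'
#' @param latitude,longitude Numeric vectors (decimal degrees).
#' @return Symmetric matrix of distances in km.
#' @export
geo_distance <- function(latitude, longitude) {
  m <- geosphere::distm(cbind(longitude, latitude),
                        fun = geosphere::distHaversine) / 1000
  rownames(m) <- colnames(m) <- names(latitude)
  m
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries with significance from
#' joint row/column permutation of one matrix (via `vegan::mantel`).
#' Optionally log-transforms the geographic matrix (`log1p`) for
#' isolation-by-distance analyses on wide spatial ranges.
#'
#' @param dist_a,dist_b Same-shape symmetric matrices (or `dist`).
#' @param n_perm Number of permutations (default 999).
#' @param log_b Apply `log1p` to `dist_b` first (default FALSE).
#' @return Object of class `pvp_mantel`: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999, log_b = FALSE) {
  A <- as.matrix(dist_a); B <- as.matrix(dist_b)
  if (!all(dim(A) == dim(B))) abort("matrices must have the same shape")
  if (log_b) B <- log1p(B)
  offdiag <- function(m) m[lower.tri(m)]
  if (sd(offdiag(A)) == 0 || sd(offdiag(B)) == 0) {
    abort("Mantel r undefined for a constant matrix")
  }
  fit <- vegan::mantel(as.dist(A), as.dist(B), method = "pearson",
                       permutations = n_perm)
  structure(list(r = unname(fit$statistic), p = fit$signif, n_perm = n_perm),
            class = "pvp_mantel")
}

#' @export
print.pvp_mantel <- function(x, ...) {
  cat(sprintf("<pvp_mantel> r = %.3f, P = %.3g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' Local spatial autocorrelation (2D-LSA)
#'
#' For each individual, the mean genetic similarity (`1 - d/d_max` over the
#' panel) to its n nearest geographic neighbors, with a one-tailed
#' permutation test (genotypes permuted across locations). The analysis is
#' swept over a range of neighborhood sizes; an individual is consistently
#' significant when `p <= alpha` at every size in the sweep. Ties in
#' geographic distance (duplicate coordinates) are broken by sample order.
#'
#' @param genetic_dist Symmetric genetic distance matrix.
#' @param latitude,longitude Sample coordinates (decimal degrees).
#' @param n_neighbors Integer vector of neighborhood sizes (default 7:14).
#' @param n_perm Number of permutations (default 999).
#' @param alpha Significance level for the consistency flag.
#' @return Object of class `pvp_lsa`: `per_individual` tibble (sample_id,
#'   n_neighbors, lr, p) and `consistency` tibble (sample_id, consistent).
#' @export
local_spatial_autocorrelation <- function(genetic_dist, latitude, longitude,
                                          n_neighbors = 7:14, n_perm = 999,
                                          alpha = 0.05) {
  G <- as.matrix(genetic_dist)
  n <- nrow(G)
  if (max(n_neighbors) >= n) abort("n_neighbors must be below the sample count")
  if (length(latitude) != n || length(longitude) != n) {
    abort("coordinates must match the distance matrix")
  }
  ids <- rownames(G) %||% as.character(seq_len(n))
  sim <- 1 - G / max(G)
  geo <- geo_distance(latitude, longitude)
  if (any(duplicated(cbind(latitude, longitude)))) {
    warn("duplicate coordinates: neighbor ties broken by sample order")
  }

  res <- purrr::map_dfr(n_neighbors, function(k) {
    nb <- t(apply(geo, 1, function(row) order(row)[2:(k + 1)]))
    lr <- map_dbl(seq_len(n), function(i) mean(sim[i, nb[i, ]]))
    ge <- rep(1L, n)  # permutation count >= observed (start with identity)
    for (b in seq_len(n_perm - 1)) {
      p <- sample.int(n)
      lrp <- rowMeans(matrix(sim[cbind(rep(p, k), p[as.vector(nb)])], n, k))
      ge <- ge + (lrp >= lr)
    }
    tibble(sample_id = ids, n_neighbors = k, lr = lr,
           p = ge / n_perm)
  })
  consistency <- res |>
    group_by(sample_id = .data$sample_id) |>
    summarise(consistent = all(.data$p <= alpha), .groups = "drop")
  structure(list(per_individual = res, consistency = consistency,
                 n_perm = n_perm, alpha = alpha),
            class = "pvp_lsa")
}

#' @export
print.pvp_lsa <- function(x, ...) {
  cat(sprintf("<pvp_lsa> %d individuals x %d neighborhood sizes; %d consistently significant (alpha = %.2f)\n",
              nrow(x$consistency),
              length(unique(x$per_individual$n_neighbors)),
              sum(x$consistency$consistent), x$alpha))
  invisible(x)
}

#' Genotype p-distance with fractional heterozygote matching
#'
#' Mean per-site dosage difference over pairwise-complete sites: a
#' heterozygote versus either homozygote counts 0.5, opposite homozygotes
#' count 1. This equals the expected mismatch of randomly drawn alleles for
#' the het-vs-hom case and is the distance used for trees and dating.
#'
#' @param geno Samples x sites dosage matrix (0, 0.5, 1, `NA`).
#' @return Symmetric distance matrix (per site).
#' @export
p_distance <- function(geno) {
  g <- as.matrix(geno)
  n <- nrow(g)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    di <- abs(sweep(g[(i + 1):n, , drop = FALSE], 2, g[i, ]))
    D[i, (i + 1):n] <- rowMeans(di, na.rm = TRUE)
  }
  D <- D + t(D)
  D[is.nan(D)] <- NA_real_
  rownames(D) <- colnames(D) <- rownames(g)
  D
}

#' UPGMA tree with column bootstrap
#'
#' Average-linkage (UPGMA) clustering on a genotype distance matrix, with
#' bootstrap support from resampling SNP columns. Input can be a genotype
#' dosage matrix (default p-distance, or TN93 on IUPAC sequences via
#' `method = "tn93"` when `sequences` are supplied) or a ready distance
#' matrix (no bootstrap).
#'
#' @param x Samples x SNPs dosage matrix, or a symmetric distance
#'   matrix / `dist` (then `n_boot` is ignored).
#' @param n_boot Bootstrap replicates (default 500; 0 disables).
#' @param method `"pdist"` (default) or `"tn93"`.
#' @param sequences Optional named character vector of IUPAC sequences
#'   (required for `"tn93"`).
#' @return Object of class `pvp_tree`: `phylo`, `newick`, `supports`
#'   (percent, internal nodes), `heights`.
#' @export
upgma_bootstrap <- function(x, n_boot = 500, method = c("pdist", "tn93"),
                            sequences = NULL) {
  method <- match.arg(method)
  is_distance <- inherits(x, "dist") ||
    (is.matrix(x) && isSymmetric(unname(as.matrix(x))) &&
       all(diag(as.matrix(x)) == 0))
  dist_fn <- function(mat) {
    if (method == "tn93") {
      dna <- ape::as.DNAbin(t(sapply(strsplit(tolower(sequences), ""), identity)))
      return(ape::dist.dna(dna, model = "TN93", pairwise.deletion = TRUE))
    }
    as.dist(p_distance(mat))
  }
  if (is_distance) {
    D <- as.dist(as.matrix(x))
    if (attr(D, "Size") < 3) abort("need at least 3 sequences")
    tree <- phangorn::upgma(D)
    supports <- NULL
  } else {
    x <- as.matrix(x)
    if (nrow(x) < 3) abort("need at least 3 sequences")
    tree <- phangorn::upgma(dist_fn(x))
    supports <- NULL
    if (n_boot > 0) {
      bp <- ape::boot.phylo(tree, x, function(m) phangorn::upgma(as.dist(p_distance(m))),
                            B = n_boot, rooted = TRUE, quiet = TRUE)
      supports <- 100 * bp / n_boot
    }
  }
  heights <- ape::node.depth.edgelength(tree)
  heights <- max(heights) - heights  # node heights above the leaves
  nwk <- ape::write.tree(tree)
  structure(list(phylo = tree, newick = nwk, supports = supports,
                 heights = heights),
            class = "pvp_tree")
}

#' @export
print.pvp_tree <- function(x, ...) {
  cat(sprintf("<pvp_tree> %d tips; UPGMA, root height %.4g%s\n",
              length(x$phylo$tip.label), max(x$heights),
              if (is.null(x$supports)) "" else
                sprintf("; mean bootstrap %.0f%%", mean(x$supports, na.rm = TRUE))))
  invisible(x)
}

#' Calibration-based divergence time
#'
#' Scales a between-group genetic distance by the distance to a calibrated
#' outgroup: `t = calibration * between / outgroup` (million years).
#'
#' @param between_group_distance Mean between-group distance
#'   (substitutions/site).
#' @param outgroup_distance Mean ingroup-to-outgroup distance (same units).
#' @param calibration_mya Calibration age of the outgroup split (default 13).
#' @return One-row tibble with the inputs and `t_mya`.
#' @export
divergence_time <- function(between_group_distance, outgroup_distance,
                            calibration_mya = 13) {
  if (any(outgroup_distance <= 0)) abort("outgroup distance must be positive")
  tibble(
    between_group_distance = between_group_distance,
    outgroup_distance = outgroup_distance,
    calibration_mya = calibration_mya,
    t_mya = calibration_mya * between_group_distance / outgroup_distance
  )
}

#' Date group splits against an outgroup calibration
#'
#' Mean between-group p-distances scaled by the mean distance of ingroup
#' genotypes to the outgroup allele profile.
#'
#' @param dataset A filtered [snp_dataset()] whose loci carry
#'   `outgroup_allele` annotations.
#' @param groups Per-sample group labels.
#' @param calibration_mya Outgroup calibration age (default 13).
#' @return Tibble of pairwise group divergence estimates.
#' @export
divergence_dating <- function(dataset, groups, calibration_mya = 13) {
  d <- dosage(dataset)
  loci <- dataset$loci
  alts <- map_chr(split_alts(loci$alt_alleles), 1)
  og <- dplyr::case_when(
    is.na(loci$outgroup_allele) ~ NA_real_,
    toupper(loci$outgroup_allele) == toupper(loci$ref_allele) ~ 0,
    toupper(loci$outgroup_allele) == toupper(alts) ~ 1,
    TRUE ~ NA_real_
  )
  if (all(is.na(og))) abort("no usable outgroup alleles")
  D <- p_distance(d)
  out_dist <- rowMeans(abs(sweep(d, 2, og)), na.rm = TRUE)
  mean_out <- mean(out_dist, na.rm = TRUE)
  gs <- unique(groups)
  purrr::map_dfr(utils::combn(gs, 2, simplify = FALSE), function(pr) {
    between <- mean(D[groups == pr[1], groups == pr[2]], na.rm = TRUE)
    divergence_time(between, mean_out, calibration_mya) |>
      mutate(group_a = pr[1], group_b = pr[2], .before = 1)
  })
}
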