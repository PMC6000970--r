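#' Simulation parameters for synthetic allotetraploid amplicon panels
#'
#' Defaults emulate the study design the package targets: 36 accessions of
#' ~10 genotypes (360 samples), 3 admixed genetic subpopulations with
#' Balding-Nichols divergence F = 0.2, 12 candidate genes of which 9 have
#' both K and N homoeologous copies (21 contigs), ~12 SNPs per 2.4 kb
#' contig (~250 SNPs), geographically structured ancestry producing
#' isolation-by-distance, Poisson read depths with binomial allele
#' fractions, and dropout missingness.
#'
#' @param n_subpops Number of genetic subpopulations.
#' @param divergence_F Balding-Nichols divergence per subpopulation.
#' @param n_accessions,samples_per_accession Panel design.
#' @param n_genes Number of genes; with `homoeolog_pairs` 3/4 of them get
#'   both K and N copies.
#' @param homoeolog_pairs Emit homoeologous contig pairs.
#' @param contig_length Contig length (bp).
#' @param snps_per_contig SNPs simulated per contig.
#' @param triallelic_prop Fraction of SNPs given a rare second alternate.
#' @param admixture_alpha Dirichlet noise on ancestry (small = purer).
#' @param range_km Geographic decay range of ancestry weights (km).
#' @param mean_depth Mean read depth at SNP sites (amplicon scale).
#' @param missing_rate Per-call dropout probability.
#' @param error_rate Per-read miscall probability.
#' @param outgroup_divergence Outgroup divergence (substitutions/site).
#' @param subgenome_divergence Sequence divergence between homoeologous K/N
#'   contig copies (substitutions/site).
#' @param outgroup_mismatch Probability the outgroup base at a SNP matches
#'   neither observed allele.
#' @param seed Random seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_subpops = 3, divergence_F = 0.2, n_accessions = 36,
                       samples_per_accession = 10, n_genes = 12,
                       homoeolog_pairs = TRUE, contig_length = 2400,
                       snps_per_contig = 12, triallelic_prop = 0.06,
                       admixture_alpha = 0.2, range_km = 500,
                       mean_depth = 30, missing_rate = 0.05,
                       error_rate = 0.01, outgroup_divergence = 0.05,
                       subgenome_divergence = 0.022,
                       outgroup_mismatch = 0.1, seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_subpops >= 1, p$divergence_F >= 0, p$divergence_F < 1,
            p$missing_rate >= 0, p$missing_rate <= 1,
            p$snps_per_contig * 2 <= p$contig_length)
  structure(p, class = "sim_params")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), alpha)
  if (sum(x) == 0) x[sample.int(length(x), 1)] <- 1
  x / sum(x)
}

subpop_anchors <- function(K) {
  # anchor points spanning the sampled range (NW -> SE gradient)
  lat <- seq(45, 30, length.out = K)
  lon <- seq(-102, -82, length.out = K)
  cbind(lat = lat, lon = lon)
}

#' Simulate a synthetic allotetraploid amplicon SNP panel
#'
#' Generates a complete [snp_dataset()] plus its ground truth. Ancestral
#' allele frequencies are Uniform(0.05, 0.95); subpopulation frequencies
#' follow the Balding-Nichols Beta distribution at the configured F;
#' per-sample ancestry is Dirichlet noise shaped by geographic proximity to
#' subpopulation anchor points (inducing isolation-by-distance); disomic
#' genotypes are drawn independently per subgenome contig; read depths are
#' Poisson and alternate fractions binomial; dropout sets depth to zero.
#' Exon/intron/UTR annotation with codon frames, reference contig
#' sequences, and an outgroup allele per SNP are emitted alongside.
#'
#' @param params A [sim_params()] list.
#' @return List with `dataset` (an `snp_dataset`), `truth` (true Q, subpop
#'   allele frequencies, haplotypes per contig, pairwise Fst from the true
#'   frequencies, coordinates), and `reference` (named vector of contig
#'   sequences).
#' @export
simulate_dataset <- function(params = sim_params()) {
  p <- params
  set.seed(p$seed)
  K <- p$n_subpops

  # ---- contig/gene layout -------------------------------------------------
  n_paired <- if (p$homoeolog_pairs) floor(0.75 * p$n_genes) else 0
  genes <- sprintf("gene%02d", seq_len(p$n_genes))
  contigs <- bind_rows(
    purrr::map_dfr(seq_len(p$n_genes), function(g) {
      sub <- if (g <= n_paired) c("K", "N") else sample(c("K", "N"), 1)
      tibble(gene = genes[g], subgenome = sub,
             contig_id = sprintf("contig_%s_%s", genes[g], sub),
             chromosome = sprintf("Chr%02d%s", (g %% 9) + 1, sub))
    })
  )

  # ---- samples, geography, ancestry --------------------------------------
  anchors <- subpop_anchors(K)
  acc_sub <- sample.int(K, p$n_accessions, replace = TRUE)
  acc_lat <- anchors[acc_sub, "lat"] + rnorm(p$n_accessions, 0, 2.5)
  acc_lon <- anchors[acc_sub, "lon"] + rnorm(p$n_accessions, 0, 2.5)
  n <- p$n_accessions * p$samples_per_accession
  samples <- tibble(
    sample_id = sprintf("g%03d", seq_len(n)),
    accession_id = rep(sprintf("acc%02d", seq_len(p$n_accessions)),
                       each = p$samples_per_accession),
    ecotype = NA_character_, ploidy = sample(c("4x", "8x", "mixed"), n,
                                             replace = TRUE,
                                             prob = c(0.45, 0.14, 0.41)),
    latitude = rep(acc_lat, each = p$samples_per_accession) + rnorm(n, 0, 0.2),
    longitude = rep(acc_lon, each = p$samples_per_accession) + rnorm(n, 0, 0.2)
  )
  samples$latitude <- pmin(pmax(samples$latitude, -90), 90)
  d_anchor <- geosphere::distm(cbind(samples$longitude, samples$latitude),
                               cbind(anchors[, "lon"], anchors[, "lat"]),
                               fun = geosphere::distHaversine) / 1000
  Q <- t(sapply(seq_len(n), function(i) {
    w <- exp(-d_anchor[i, ] / p$range_km)
    eps <- rdirichlet1(rep(p$admixture_alpha, K))
    q <- w * eps
    q / sum(q)
  }))
  # ecotype follows the dominant ancestry: northern clusters upland
  dominant <- apply(Q, 1, which.max)
  samples$ecotype <- ifelse(anchors[dominant, "lat"] >= median(anchors[, "lat"]),
                            "upland", "lowland")

  # ---- loci ---------------------------------------------------------------
  bases <- c("A", "C", "G", "T")
  mutate_seq <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    hit <- which(runif(length(v)) < rate)
    v[hit] <- map_chr(hit, function(i) sample(setdiff(bases, v[i]), 1))
    paste(v, collapse = "")
  }
  gene_base <- setNames(
    map_chr(genes, function(g)
      paste(sample(bases, p$contig_length, replace = TRUE), collapse = "")),
    genes)
  loci_list <- list(); truth_haps <- list(); ref_seqs <- character()
  og_seqs <- character(); freq_list <- list()
  for (ci in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[ci]
    refseq <- gene_base[[contigs$gene[ci]]]
    if (contigs$subgenome[ci] == "N" && contigs$gene[ci] %in%
          contigs$gene[duplicated(contigs$gene)]) {
      refseq <- mutate_seq(refseq, p$subgenome_divergence)
    }
    ref_seqs[cid] <- refseq
    og_seqs[cid] <- mutate_seq(refseq, p$outgroup_divergence)
    # annotation: UTR5 | exon1 | intron | exon2 | UTR3
    b1 <- round(p$contig_length * 0.1); b2 <- round(p$contig_length * 0.4)
    b3 <- round(p$contig_length * 0.6); b4 <- round(p$contig_length * 0.9)
    region_of <- function(pos) {
      dplyr::case_when(pos <= b1 ~ "UTR5",
                       pos <= b2 ~ "exon",
                       pos <= b3 ~ "intron",
                       pos <= b4 ~ "exon",
                       TRUE ~ "UTR3")
    }
    coding_pos <- function(pos) {
      ifelse(pos <= b2, pos - b1, (b2 - b1) + (pos - b3))
    }
    pos <- sort(sample(seq(3, p$contig_length - 3, by = 2),
                       p$snps_per_contig))
    ref_al <- strsplit(refseq, "")[[1]][pos]
    alt_al <- map_chr(ref_al, function(r) sample(setdiff(bases, r), 1))
    tri <- runif(p$snps_per_contig) < p$triallelic_prop
    alt2_al <- ifelse(tri, map_chr(seq_along(ref_al), function(i)
      sample(setdiff(bases, c(ref_al[i], alt_al[i])), 1)), NA_character_)
    reg <- region_of(pos)
    frame <- ifelse(reg == "exon", (coding_pos(pos) - 1) %% 3, NA_integer_)

    p0 <- runif(p$snps_per_contig, 0.05, 0.95)
    F <- p$divergence_F
    pk <- if (F > 0) {
      sapply(p0, function(q) rbeta(K, q * (1 - F) / F, (1 - q) * (1 - F) / F))
    } else {
      matrix(rep(p0, each = K), nrow = K)
    }
    if (K == 1) pk <- matrix(pk, nrow = 1)
    freq_list[[cid]] <- pk

    ancestral <- ifelse(p0 < 0.5, ref_al, alt_al)
    og <- ancestral
    third <- runif(p$snps_per_contig) < p$outgroup_mismatch
    og[third] <- map_chr(which(third), function(i)
      sample(setdiff(bases, c(ref_al[i], alt_al[i])), 1))

    loci_list[[cid]] <- tibble(
      locus_id = sprintf("%s_p%04d", cid, pos),
      contig_id = cid, gene = contigs$gene[ci],
      chromosome = contigs$chromosome[ci],
      subgenome = contigs$subgenome[ci],
      position = pos, ref_allele = ref_al,
      alt_alleles = ifelse(tri, paste(alt_al, alt2_al, sep = ","), alt_al),
      region = reg, codon_frame = as.integer(frame),
      outgroup_allele = og, strand = "+", tri = tri
    )

    # haplotypes: each allele copy draws its origin from Q then its allele
    h1 <- matrix(0L, n, p$snps_per_contig)
    h2 <- matrix(0L, n, p$snps_per_contig)
    for (i in seq_len(n)) {
      zi1 <- sample.int(K, p$snps_per_contig, replace = TRUE, prob = Q[i, ])
      zi2 <- sample.int(K, p$snps_per_contig, replace = TRUE, prob = Q[i, ])
      h1[i, ] <- rbinom(p$snps_per_contig, 1,
                        pk[cbind(zi1, seq_len(p$snps_per_contig))])
      h2[i, ] <- rbinom(p$snps_per_contig, 1,
                        pk[cbind(zi2, seq_len(p$snps_per_contig))])
    }
    truth_haps[[cid]] <- list(h1 = h1, h2 = h2)
  }
  loci <- bind_rows(loci_list)
  L <- nrow(loci)

  # ---- reads --------------------------------------------------------------
  gmat <- do.call(cbind, map(names(truth_haps), function(cid) {
    (truth_haps[[cid]]$h1 + truth_haps[[cid]]$h2) / 2
  }))
  depth <- matrix(rpois(n * L, p$mean_depth), n, L)
  depth[matrix(runif(n * L) < p$missing_rate, n, L)] <- 0L
  e <- p$error_rate
  frac_true <- gmat * (1 - 2 * e) + e
  alt_reads <- matrix(rbinom(n * L, as.vector(depth), as.vector(frac_true)),
                      n, L)
  alt_fraction <- ifelse(depth > 0, alt_reads / depth, NA_real_)

  # rare second alternate: a small share of alt reads at triallelic loci
  alt2_fraction <- matrix(0, n, L)
  tri_cols <- which(loci$tri)
  for (j in tri_cols) {
    carriers <- which(gmat[, j] > 0 & depth[, j] > 0)
    take <- carriers[runif(length(carriers)) < 0.15]
    alt2_reads <- rbinom(length(take), round(alt_fraction[take, j] *
                                               depth[take, j]), 0.5)
    alt2_fraction[take, j] <- alt2_reads / depth[take, j]
  }
  loci$tri <- NULL

  ds <- snp_dataset(samples, loci, depth, alt_fraction,
                    alt2_fraction = alt2_fraction)

  # ---- truth --------------------------------------------------------------
  true_fst <- NULL
  if (K >= 2) {
    pf <- do.call(cbind, freq_list)  # K x L true subpop frequencies
    true_fst <- matrix(0, K, K,
                       dimnames = list(paste0("C", 1:K), paste0("C", 1:K)))
    for (a in seq_len(K - 1)) for (b in (a + 1):K) {
      true_fst[a, b] <- true_fst[b, a] <-
        gst_from_freqs(pf[c(a, b), , drop = FALSE])
    }
  }
  colnames(Q) <- paste0("C", seq_len(K))
  rownames(Q) <- samples$sample_id

  list(
    dataset = ds,
    truth = list(Q = Q, subpop_freqs = freq_list, haplotypes = truth_haps,
                 fst = true_fst, params = p,
                 subpop = paste0("C", apply(Q, 1, which.max))),
    reference = ref_seqs,
    outgroup_sequences = og_seqs
  )
}

perms_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in perms_of(k - 1)) {
      out[[length(out) + 1]] <- c(i, setdiff(seq_len(k), i)[rest])
    }
  }
  out
}

#' Ancestry recovery error after optimal label matching
#'
#' Root-mean-square difference between an estimated and a true Q matrix,
#' minimized over cluster relabelings.
#'
#' @param Q_est,Q_true Samples x K membership matrices.
#' @return RMSE (scalar).
#' @export
q_rmse <- function(Q_est, Q_true) {
  stopifnot(all(dim(Q_est) == dim(Q_true)))
  K <- ncol(Q_true)
  min(map_dbl(perms_of(K), function(pm) {
    sqrt(mean((Q_est[, pm, drop = FALSE] - Q_true)^2))
  }))
}

#' Recovery metrics against simulation truth
#'
#' @param truth The `truth` element of [simulate_dataset()].
#' @param admixture Optional `pvp_admixture` fit on the same samples.
#' @param fst Optional estimated pairwise Fst matrix (same subpop order).
#' @return Tibble of metric/value rows.
#' @export
truth_report <- function(truth, admixture = NULL, fst = NULL) {
  rows <- list()
  if (!is.null(admixture)) {
    if (nrow(admixture$Q) != nrow(truth$Q)) abort("sample sets differ")
    rows$q_rmse <- q_rmse(admixture$Q, truth$Q)
  }
  if (!is.null(fst) && !is.null(truth$fst)) {
    dif <- fst[upper.tri(fst)] - truth$fst[upper.tri(truth$fst)]
    rows$fst_bias <- mean(dif)
    rows$fst_rmse <- sqrt(mean(dif^2))
  }
  tibble(metric = names(rows), value = unname(unlist(rows)))
}
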