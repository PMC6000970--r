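#' Fit the admixture model by Gibbs sampling
#'
#' STRUCTURE-style Bayesian clustering: each allele copy has a latent
#' cluster of origin drawn from the individual's ancestry vector
#' `q_i ~ Dirichlet(alpha)`, and cluster allele frequencies have independent
#' uniform priors. The sampler returns posterior-mean ancestry (Q) and
#' allele-frequency (P) matrices and the model log-probability of the data
#' `LnP(D) = mean(lnL) - var(lnL)/2` over post-burn-in iterations. With
#' several runs the reporting run is picked by `run_selection` (highest
#' LnP(D) by default; "lowest" is available for protocols that used it).
#'
#' @param dataset A filtered [snp_dataset()] or a samples x loci dosage
#'   matrix.
#' @param K Number of clusters (>= 1).
#' @param n_burnin,n_iter Burn-in and retained MCMC iterations.
#' @param n_runs Independent runs (default 1).
#' @param alpha Dirichlet admixture parameter (default 1).
#' @param seed Optional integer; run r uses `seed + r - 1`.
#' @param run_selection `"highest"` (default) or `"lowest"` LnP(D).
#' @return Object of class `pvp_admixture` with `K`, `Q`, `P`,
#'   `lnPD_per_run`, `chosen_run`.
#' @export
fit_admixture <- function(dataset, K, n_burnin = 1000, n_iter = 2000,
                          n_runs = 1, alpha = 1, seed = NULL,
                          run_selection = c("highest", "lowest")) {
  run_selection <- match.arg(run_selection)
  d <- if (inherits(dataset, "snp_dataset")) dosage(dataset) else as.matrix(dataset)
  if (K < 1) abort("K must be >= 1")
  if (K > nrow(d)) abort("K cannot exceed the number of samples")
  geno <- round(2 * d)
  mode(geno) <- "integer"

  runs <- map(seq_len(n_runs), function(r) {
    if (!is.null(seed)) set.seed(seed + r - 1)
    fit <- admixture_gibbs_cpp(geno, K, n_burnin, n_iter, alpha)
    lnl <- fit$lnL
    fit$lnPD <- mean(lnl) - var(lnl) / 2
    if (n_iter == 1) fit$lnPD <- mean(lnl)
    fit
  })
  lnpd <- map_dbl(runs, "lnPD")
  chosen <- if (run_selection == "highest") which.max(lnpd) else which.min(lnpd)
  fit <- runs[[chosen]]
  rownames(fit$Q) <- rownames(d)
  colnames(fit$Q) <- paste0("C", seq_len(K))
  rownames(fit$P) <- paste0("C", seq_len(K))
  colnames(fit$P) <- colnames(d)
  structure(
    list(K = K, Q = fit$Q, P = fit$P, lnPD_per_run = lnpd,
         chosen_run = chosen, run_selection = run_selection,
         n_burnin = n_burnin, n_iter = n_iter, alpha = alpha),
    class = "pvp_admixture"
  )
}

#' @export
print.pvp_admixture <- function(x, ...) {
  cat(sprintf(
    "<pvp_admixture> K = %d, %d samples; LnP(D) = %.2f (run %d of %d)\n",
    x$K, nrow(x$Q), x$lnPD_per_run[x$chosen_run], x$chosen_run,
    length(x$lnPD_per_run)))
  invisible(x)
}

#' Choose K from LnP(D) summaries
#'
#' The ad hoc criterion: the K maximizing mean LnP(D) over runs, with
#' plateau detection - the smallest K whose mean lies within one standard
#' deviation (of the best K's runs) of the maximum is reported.
#'
#' @param lnpd Tibble with columns `K` and `lnPD` (one row per run).
#' @return The selected K (integer).
#' @export
select_k <- function(lnpd) {
  stopifnot(all(c("K", "lnPD") %in% names(lnpd)))
  if (length(unique(lnpd$K)) == 1) {
    warn("only one K evaluated; returning it")
    return(unique(lnpd$K))
  }
  summ <- lnpd |>
    group_by(K = .data$K) |>
    summarise(mean_lnpd = mean(.data$lnPD), sd_lnpd = sd(.data$lnPD),
              .groups = "drop") |>
    arrange(.data$K)
  best <- summ$K[which.max(summ$mean_lnpd)]
  tol <- summ$sd_lnpd[summ$K == best]
  if (is.na(tol)) tol <- 0
  cand <- summ$K[summ$mean_lnpd >= max(summ$mean_lnpd) - tol]
  min(cand)
}

#' Assign samples to subpopulations with the 70% rule
#'
#' Each sample goes to its argmax cluster; samples whose maximum membership
#' is below `threshold` are `admixed`. An accession is representative of a
#' subpopulation when more than `threshold` of its genotypes are assigned
#' there.
#'
#' @param fit A `pvp_admixture` object.
#' @param accessions Optional per-sample accession labels (in `Q` row
#'   order).
#' @param threshold Membership threshold (default 0.70).
#' @return List with `membership` tibble (sample_id, assigned, max_q) and
#'   `representatives` tibble (accession, subpopulation, prop).
#' @export
classify_membership <- function(fit, accessions = NULL, threshold = 0.70) {
  stopifnot(inherits(fit, "pvp_admixture"))
  Q <- fit$Q
  maxq <- apply(Q, 1, max)
  arg <- colnames(Q)[apply(Q, 1, which.max)]
  membership <- tibble(
    sample_id = rownames(Q) %||% as.character(seq_len(nrow(Q))),
    assigned = unname(ifelse(maxq < threshold, "admixed", arg)),
    max_q = unname(maxq)
  )
  reps <- NULL
  if (!is.null(accessions)) {
    reps <- membership |>
      mutate(accession = accessions) |>
      group_by(.data$accession) |>
      summarise(
        subpopulation = names(which.max(table(.data$assigned))),
        prop = max(table(.data$assigned)) / n(), .groups = "drop") |>
      filter(.data$prop > threshold, .data$subpopulation != "admixed")
  }
  list(membership = membership, representatives = reps)
}

#' Pairwise genetic distance between individuals
#'
#' Square root of the squared-dosage distance (the same metric the AMOVA
#' uses at the allele level): per-locus squared dosage differences summed
#' over pairwise-complete loci and rescaled to the full locus count.
#'
#' @param dataset A filtered [snp_dataset()] or dosage matrix.
#' @return A symmetric distance matrix.
#' @export
genetic_distance <- function(dataset) {
  d <- if (inherits(dataset, "snp_dataset")) dosage(dataset) else as.matrix(dataset)
  D2 <- gamete_sqdist(d)  # works for any numeric matrix with NAs
  D <- sqrt(pmax(D2, 0))
  rownames(D) <- colnames(D) <- rownames(d)
  D
}

#' Principal coordinates analysis
#'
#' Double-centering eigen-decomposition of a symmetric distance matrix;
#' axis variance percentages are computed from the positive eigenvalues.
#'
#' @param D Symmetric distance matrix (or `dist`).
#' @param n_axes Number of axes to keep (default all positive).
#' @return Object of class `pvp_pcoa` with `coordinates`, `eigenvalues`,
#'   `pct_variance`.
#' @export
pcoa <- function(D, n_axes = NULL) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) abort("distance matrix must be symmetric")
  n <- nrow(D)
  fit <- suppressWarnings(cmdscale(as.dist(D), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > 1e-8 * max(abs(eig))
  pct <- 100 * eig[pos] / sum(eig[pos])
  coords <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  if (!is.null(n_axes)) {
    keep <- seq_len(min(n_axes, ncol(coords)))
    coords <- coords[, keep, drop = FALSE]
  }
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(
    list(coordinates = coords, eigenvalues = eig[pos],
         pct_variance = pct),
    class = "pvp_pcoa"
  )
}

#' @export
print.pvp_pcoa <- function(x, ...) {
  cat(sprintf("<pvp_pcoa> %d samples, %d positive axes; axis 1-3: %s%%\n",
              nrow(x$coordinates), length(x$eigenvalues),
              paste(sprintf("%.1f", head(x$pct_variance, 3)), collapse = "/")))
  invisible(x)
}
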