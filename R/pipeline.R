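#' Pipeline configuration
#'
#' Every threshold of the analysis with its standard default. MCMC and
#' permutation counts default to full protocol scale (100k burn-in / 100k
#' iterations, 10 runs over K = 1..10, 999 permutations, 9999 for the
#' 2D-LSA, 500 bootstrap replicates); reduce them for quick runs.
#'
#' @param ... Overrides for any default (see `pvp_config()` output).
#' @return A `pvp_config` list.
#' @export
pvp_config <- function(...) {
  cfg <- list(
    maf_lo = 0.05, maf_hi = 0.95, max_missing = 0.20, min_depth = 3,
    max_sample_missing = 0.30,
    conservation_threshold = 1,
    k_range = 1:10, n_burnin = 1e5, n_iter = 1e5, n_runs = 10, alpha = 1,
    run_selection = "highest", membership_threshold = 0.70,
    n_perm = 999, lsa_n_perm = 9999, lsa_neighbors = 7:14,
    tree_boot = 500, calibration_mya = 13,
    run_lsa = TRUE, run_tree = TRUE,
    seed = 1L,
    sim = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) abort(paste0("unknown config field(s): ",
                                    paste(unknown, collapse = ", ")))
  structure(modifyList(cfg, over), class = "pvp_config")
}

stage_msg <- function(...) message(sprintf(...))

#' Run the full analysis pipeline
#'
#' Executes filter -> classify -> diversity -> structure -> differentiation
#' -> phylogeography -> subgenome contrast in order on loaded or simulated
#' data, logging per-stage counts to stderr. Deterministic given
#' `config$seed`.
#'
#' @param config A [pvp_config()].
#' @param input Either `NULL` (simulate with `config$sim` /
#'   [sim_params()]), a list from [simulate_dataset()], or a named list of
#'   file paths (`vcf`, `metadata`, `annotation`, optionally `reference`,
#'   `outgroup`) for [load_dataset()].
#' @param out_dir Optional directory; when given, [export_tables()] writes
#'   all table layouts there.
#' @return Named list of results (class `pvp_results`).
#' @export
run_pipeline <- function(config = pvp_config(), input = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pvp_config"))
  set.seed(config$seed)
  res <- list(config = config)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # ---- input --------------------------------------------------------------
  reference <- NULL; truth <- NULL
  if (is.null(input) || inherits(input, "sim_params")) {
    prm <- if (inherits(input, "sim_params")) input
           else config$sim %||% sim_params(seed = config$seed)
    stage_msg("simulate: %d accessions x %d samples", prm$n_accessions,
              prm$samples_per_accession)
    sim <- simulate_dataset(prm)
    ds <- sim$dataset; reference <- sim$reference; truth <- sim$truth
    res$outgroup_sequences <- sim$outgroup_sequences
  } else if (is.list(input) && !is.null(input$dataset)) {
    ds <- input$dataset; reference <- input$reference
    truth <- input$truth; res$outgroup_sequences <- input$outgroup_sequences
  } else {
    ds <- run_stage("load", load_dataset(
      input$vcf, input$metadata, input$annotation,
      reference_path = input$reference, outgroup_path = input$outgroup))
    reference <- attr(ds, "reference")
  }
  stage_msg("input: %d samples x %d variants", nrow(ds$samples),
            nrow(ds$loci))
  res$truth <- truth

  # ---- filter -------------------------------------------------------------
  flt <- run_stage("filter", {
    sf <- apply_site_filters(ds, config$maf_lo, config$maf_hi,
                             config$max_missing, config$min_depth)
    smp <- apply_sample_filter(sf$dataset, config$max_sample_missing)
    rep <- sf$report
    rep$n_samples_removed <- smp$report$n_samples_removed
    list(dataset = smp$dataset, report = rep)
  })
  ds <- flt$dataset
  res$filter_report <- flt$report
  res$dataset <- ds
  stage_msg("filter: %d SNPs retained, %d samples retained",
            nrow(ds$loci), nrow(ds$samples))

  # ---- structure (needed early: classification uses subpopulations) -------
  strs <- run_stage("structure", {
    lnpd <- purrr::map_dfr(config$k_range, function(K) {
      fit <- fit_admixture(ds, K, config$n_burnin, config$n_iter,
                           config$n_runs, config$alpha,
                           seed = config$seed + 97L * K,
                           run_selection = config$run_selection)
      tibble(K = K, run = seq_along(fit$lnPD_per_run),
             lnPD = fit$lnPD_per_run, fit = list(fit))
    })
    Kbest <- if (length(config$k_range) > 1) {
      select_k(lnpd)
    } else {
      config$k_range
    }
    fit <- lnpd$fit[[which(lnpd$K == Kbest)[1]]]
    mem <- classify_membership(fit, ds$samples$accession_id,
                               config$membership_threshold)
    list(lnpd = select(lnpd, -"fit"), K = Kbest, fit = fit, mem = mem)
  })
  res$lnpd <- strs$lnpd
  res$admixture <- strs$fit
  res$K <- strs$K
  res$membership <- strs$mem$membership |>
    bind_cols(as_tibble(strs$fit$Q)) |>
    mutate(accession_id = ds$samples$accession_id,
           ecotype = ds$samples$ecotype)
  res$representative_accessions <- strs$mem$representatives
  subpop <- ifelse(strs$mem$membership$assigned == "admixed",
                   colnames(strs$fit$Q)[apply(strs$fit$Q, 1, which.max)],
                   strs$mem$membership$assigned)
  stage_msg("structure: K = %d, %d admixed individuals", strs$K,
            sum(strs$mem$membership$assigned == "admixed"))

  # ---- classification -----------------------------------------------------
  res$snp_classification <- run_stage("classify",
    classify_snps(ds, reference = reference, subpop = subpop))
  stage_msg("classify: %d nonsynonymous, %d non-conservative",
            sum(res$snp_classification$effect == "nonsynonymous"),
            sum(res$snp_classification$conservation == "non_conservative"))

  # ---- diversity ----------------------------------------------------------
  div <- run_stage("diversity", {
    contig_len <- if (!is.null(reference)) nchar(reference) else NULL
    per_contig <- purrr::map_dfr(unique(ds$loci$contig_id), function(cid) {
      sel <- ds$loci$contig_id == cid
      g <- dosage(ds)[, sel, drop = FALSE]
      ph <- phase_haplotypes(g)
      L <- if (!is.null(contig_len) && cid %in% names(contig_len))
        contig_len[[cid]] else max(ds$loci$position[sel])
      cls <- res$snp_classification[sel, ]
      sequence_diversity(ph, L) |>
        mutate(contig_id = cid, gene = ds$loci$gene[sel][1],
               chromosome = ds$loci$chromosome[sel][1],
               subgenome = ds$loci$subgenome[sel][1],
               non_cod = sum(cls$effect == "noncoding"),
               syn = sum(cls$effect == "synonymous"),
               con = sum(cls$conservation == "conservative"),
               non_con = sum(cls$conservation == "non_conservative"),
               .before = 1)
    })
    per_contig
  })
  res$gene_diversity <- div
  res$subpop_diversity <- run_stage("diversity_groups",
                                    diversity_summary(ds, subpop))
  stage_msg("diversity: %d contigs summarised", nrow(div))

  # ---- differentiation ----------------------------------------------------
  res$gst <- run_stage("gst",
    gst_overall(ds, ds$samples$accession_id, n_perm = config$n_perm))
  res$pairwise <- run_stage("pairwise",
    pairwise_differentiation(ds, subpop))
  fstm <- res$pairwise$fst
  diag(fstm) <- NA
  res$nm_pairwise <- suppressWarnings(gene_flow_nm(fstm))
  res$amova <- run_stage("amova", {
    lat_bin <- paste0("lat", floor(ds$samples$latitude))
    list(
      subpopulation = amova(ds, subpop, n_perm = config$n_perm),
      accession = amova(ds, ds$samples$accession_id, n_perm = config$n_perm),
      latitude_bin = amova(ds, lat_bin, n_perm = config$n_perm)
    )
  })
  stage_msg("differentiation: Gst = %.3f (P = %.3g)", res$gst$gst,
            res$gst$p)

  # ---- phylogeography -----------------------------------------------------
  gd <- genetic_distance(ds)
  geo <- geo_distance(ds$samples$latitude, ds$samples$longitude)
  res$mantel <- run_stage("mantel",
    mantel_test(gd, geo, n_perm = config$n_perm))
  if (isTRUE(config$run_lsa)) {
    res$lsa <- run_stage("lsa", local_spatial_autocorrelation(
      gd, ds$samples$latitude, ds$samples$longitude,
      n_neighbors = config$lsa_neighbors, n_perm = config$lsa_n_perm))
  }
  if (isTRUE(config$run_tree)) {
    res$tree <- run_stage("tree",
      upgma_bootstrap(dosage(ds), n_boot = config$tree_boot))
  }
  res$divergence <- run_stage("divergence",
    divergence_dating(ds, subpop, config$calibration_mya))
  stage_msg("phylogeo: Mantel r = %.3f (P = %.3g)", res$mantel$r,
            res$mantel$p)

  # ---- subgenome ----------------------------------------------------------
  res$subgenome <- run_stage("subgenome", {
    contig_len <- if (!is.null(reference))
      setNames(nchar(reference), names(reference)) else NULL
    contrast <- homoeolog_contrast_table(ds, contig_len)
    windows <- purrr::map_dfr(unique(ds$loci$contig_id), function(cid) {
      sel <- ds$loci$contig_id == cid
      L <- if (!is.null(contig_len) && cid %in% names(contig_len))
        contig_len[[cid]] else max(ds$loci$position[sel])
      window_variant_profile(ds$loci[sel, ], L) |>
        mutate(contig_id = cid, .before = 1)
    })
    sub_t <- NULL
    if (!is.null(reference) && !is.null(res$outgroup_sequences)) {
      sub_t <- subgenome_divergence(ds$loci, reference,
                                    res$outgroup_sequences,
                                    config$calibration_mya)
    }
    list(contrast = contrast, windows = windows, divergence = sub_t)
  })
  stage_msg("subgenome: %d genes contrasted",
            nrow(res$subgenome$contrast))

  class(res) <- "pvp_results"
  if (!is.null(out_dir)) export_tables(res, out_dir)
  res
}

#' @export
print.pvp_results <- function(x, ...) {
  cat(sprintf(
    "<pvp_results> %d samples x %d SNPs | K = %d | Gst = %.3f | Mantel r = %.3f\n",
    nrow(x$dataset$samples), nrow(x$dataset$loci), x$K, x$gst$gst,
    x$mantel$r))
  invisible(x)
}

#' Date the K/N subgenome split from homoeologous consensus sequences
#'
#' Per gene with both homoeologs, the p-distance between the K and N
#' reference (consensus) sequences scaled by the mean reference-to-outgroup
#' distance: `t = calibration * d_KN / d_outgroup`. Symmetric in K and N by
#' construction.
#'
#' @param loci Locus table carrying `gene`, `subgenome`, `contig_id`.
#' @param reference,outgroup_sequences Named vectors of contig and matched
#'   outgroup sequences.
#' @param calibration_mya Calibration age (default 13).
#' @return Tibble with per-gene `d_KN`, `d_outgroup`, `t_mya`.
#' @export
subgenome_divergence <- function(loci, reference, outgroup_sequences,
                                 calibration_mya = 13) {
  seq_mismatch <- function(a, b) {
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    L <- min(length(va), length(vb))
    mean(va[seq_len(L)] != vb[seq_len(L)])
  }
  pairs <- loci |>
    distinct(.data$gene, .data$subgenome, .data$contig_id) |>
    filter(.data$subgenome %in% c("K", "N")) |>
    tidyr::pivot_wider(names_from = "subgenome",
                       values_from = "contig_id") |>
    filter(!is.na(.data$K), !is.na(.data$N))
  if (nrow(pairs) == 0) return(NULL)
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    ck <- pairs$K[i]; cn <- pairs$N[i]
    d_kn <- seq_mismatch(reference[[ck]], reference[[cn]])
    d_out <- mean(c(seq_mismatch(reference[[ck]], outgroup_sequences[[ck]]),
                    seq_mismatch(reference[[cn]], outgroup_sequences[[cn]])))
    tibble(gene = pairs$gene[i], d_KN = d_kn, d_outgroup = d_out,
           t_mya = if (d_out > 0) calibration_mya * d_kn / d_out else NA_real_)
  })
}
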