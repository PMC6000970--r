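#' Load a variant panel from standard files
#'
#' Reads a multi-sample VCF (AD per-sample allele depths required; GT
#' optional and ignored - zygosity is recalled from read fractions), a
#' tab-delimited sample metadata table, a BED-like annotation table, and
#' optional reference/outgroup files into an [snp_dataset()]. Alt fractions
#' are computed as summed alternate depth over total depth; loci are
#' annotated with gene, subgenome, region and codon frame by interval
#' lookup; outgroup alleles are attached where provided.
#'
#' The annotation table needs columns `contig_id, start, end, gene,
#' subgenome, region, frame_start, strand` (1-based inclusive intervals;
#' `frame_start` is the codon offset of the interval's first base, `NA`
#' outside coding regions). The outgroup file is either a two-column-style
#' TSV (`contig_id, position, outgroup_allele`) or a FASTA aligned to the
#' reference contigs, in which case the aligned base at each SNP position
#' is used.
#'
#' @param vcf_path,metadata_path,annotation_path File paths.
#' @param reference_path Optional FASTA of contig sequences.
#' @param outgroup_path Optional outgroup TSV or FASTA.
#' @return An [snp_dataset()]; the reference sequences (if given) are
#'   attached as `attr(x, "reference")`.
#' @export
load_dataset <- function(vcf_path, metadata_path, annotation_path,
                         reference_path = NULL, outgroup_path = NULL) {
  for (f in c(vcf_path, metadata_path, annotation_path)) {
    if (!file.exists(f)) abort(paste0("file not found: ", f))
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  vcf_samples <- colnames(ad)

  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  missing_samples <- setdiff(vcf_samples, meta$sample_id)
  if (length(missing_samples)) {
    abort(paste0("VCF sample(s) absent from metadata: ",
                 paste(missing_samples, collapse = ", ")))
  }
  meta <- meta[match(vcf_samples, meta$sample_id), ]

  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE)

  pos <- as.integer(fix$POS)
  loci <- tibble(
    contig_id = fix$CHROM, position = pos,
    ref_allele = fix$REF, alt_alleles = fix$ALT
  )
  # interval lookup
  hit <- purrr::pmap(list(loci$contig_id, loci$position), function(ct, ps) {
    rows <- ann[ann$contig_id == ct & ann$start <= ps & ann$end >= ps, ]
    if (nrow(rows) == 0) return(NULL)
    rows[1, ]
  })
  orphan <- map_lgl(hit, is.null)
  if (any(orphan)) {
    warn(sprintf("%d locus/loci outside annotated intervals: region set to intergenic",
                 sum(orphan)))
  }
  ann_field <- function(field, default) {
    map_chr(hit, function(h) if (is.null(h)) default else as.character(h[[field]]))
  }
  loci <- loci |> mutate(
    gene = ann_field("gene", NA_character_),
    subgenome = ann_field("subgenome", "unknown"),
    region = ann_field("region", "intergenic"),
    strand = ann_field("strand", "+"),
    chromosome = NA_character_,
    codon_frame = {
      fs <- suppressWarnings(as.integer(ann_field("frame_start", NA)))
      st <- map_int(hit, function(h) if (is.null(h)) NA_integer_
                    else as.integer(h$start))
      ifelse(.data$region == "exon" & !is.na(fs),
             (fs + (.data$position - st)) %% 3L, NA_integer_)
    },
    outgroup_allele = NA_character_,
    locus_id = sprintf("%s_p%04d", .data$contig_id, .data$position)
  )

  if (!is.null(outgroup_path)) {
    if (grepl("\\.(fa|fasta|fna)$", outgroup_path, ignore.case = TRUE)) {
      og <- Biostrings::readDNAStringSet(outgroup_path)
      ogc <- setNames(as.character(og), sub(" .*", "", names(og)))
      loci$outgroup_allele <- toupper(substr(
        ogc[loci$contig_id], loci$position, loci$position))
    } else {
      ogt <- readr::read_tsv(outgroup_path, show_col_types = FALSE)
      key <- paste(loci$contig_id, loci$position)
      m <- match(key, paste(ogt$contig_id, ogt$position))
      loci$outgroup_allele <- toupper(ogt$outgroup_allele[m])
    }
    loci$outgroup_allele[loci$outgroup_allele %in% c("", "N", "-")] <- NA
  }

  # AD fields: ref,alt1[,alt2]
  parse_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x), "", x), ",")
    vals <- map(parts, function(v) suppressWarnings(as.numeric(v)))
    list(
      tot = map_dbl(vals, function(v) if (!length(v) || anyNA(v)) 0 else sum(v)),
      alt = map_dbl(vals, function(v) if (length(v) < 2 || anyNA(v)) 0
                    else sum(v[-1])),
      alt2 = map_dbl(vals, function(v) if (length(v) < 3 || anyNA(v)) 0
                     else v[3])
    )
  }
  n <- length(vcf_samples); L <- nrow(loci)
  depth <- matrix(0L, n, L); altf <- matrix(NA_real_, n, L)
  alt2f <- matrix(0, n, L)
  for (j in seq_len(L)) {
    p <- parse_ad(ad[j, ])
    depth[, j] <- as.integer(p$tot)
    altf[, j] <- ifelse(p$tot > 0, p$alt / p$tot, NA_real_)
    alt2f[, j] <- ifelse(p$tot > 0, p$alt2 / p$tot, 0)
  }

  ds <- snp_dataset(meta, loci, depth, altf, alt2_fraction = alt2f)
  if (!is.null(reference_path)) {
    rs <- Biostrings::readDNAStringSet(reference_path)
    attr(ds, "reference") <- setNames(as.character(rs),
                                      sub(" .*", "", names(rs)))
  }
  ds
}

#' Write a dataset (and companions) to standard files
#'
#' Emits `variants.vcf` (VCF v4.2 with AD), `metadata.tsv`,
#' `annotation.tsv` (BED-like interval table readable by
#' [load_dataset()]), `reference.fasta` and `outgroup.tsv`.
#'
#' @param dataset An [snp_dataset()].
#' @param dir Output directory (created if needed).
#' @param reference Optional named character vector of contig sequences.
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir, reference = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ds <- dataset
  files <- c()

  # VCF
  vcf_path <- file.path(dir, "variants.vcf")
  con <- file(vcf_path, "w")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pvpopgen",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$samples$sample_id), collapse = "\t")), con)
  a2 <- ds$alt2_fraction
  for (j in seq_len(nrow(ds$loci))) {
    dp <- ds$depth[, j]; af <- ds$alt_fraction[, j]
    af2 <- if (is.null(a2)) rep(0, length(dp)) else a2[, j]
    alt_tot <- ifelse(dp > 0, round(af * dp), 0)
    alt2_r <- ifelse(dp > 0, round(af2 * dp), 0)
    alt1_r <- alt_tot - alt2_r
    ref_r <- dp - alt_tot
    alts <- split_alts(ds$loci$alt_alleles[j])[[1]]
    cells <- if (length(alts) > 1) {
      paste(ref_r, alt1_r, alt2_r, sep = ",")
    } else {
      paste(ref_r, alt1_r, sep = ",")
    }
    cells[dp == 0] <- if (length(alts) > 1) "0,0,0" else "0,0"
    writeLines(paste(c(ds$loci$contig_id[j], ds$loci$position[j],
                       ds$loci$locus_id[j], ds$loci$ref_allele[j],
                       paste(alts, collapse = ","), ".", "PASS", ".",
                       "AD", cells), collapse = "\t"), con)
  }
  close(con)
  files <- c(files, vcf_path)

  meta_path <- file.path(dir, "metadata.tsv")
  readr::write_tsv(ds$samples, meta_path)
  ann_path <- file.path(dir, "annotation.tsv")
  ann <- ds$loci |>
    transmute(contig_id = .data$contig_id, start = .data$position,
              end = .data$position, gene = .data$gene,
              subgenome = .data$subgenome, region = .data$region,
              frame_start = .data$codon_frame,
              strand = if ("strand" %in% names(ds$loci)) .data$strand else "+")
  readr::write_tsv(ann, ann_path)
  og_path <- file.path(dir, "outgroup.tsv")
  readr::write_tsv(ds$loci |>
                     select("contig_id", "position", "outgroup_allele"),
                   og_path)
  files <- c(files, meta_path, ann_path, og_path)

  if (!is.null(reference)) {
    ref_path <- file.path(dir, "reference.fasta")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(reference), ref_path)
    files <- c(files, ref_path)
  }
  invisible(files)
}

#' @importFrom dplyr transmute
write_or_header <- function(df, path) {
  readr::write_tsv(df, path)
  path
}

#' Export pipeline result tables
#'
#' Writes the standard table layouts as tab-delimited text: per-gene
#' diversity, per-SNP classification, per-subpopulation diversity, pairwise
#' differentiation (Nei distance upper triangle, Fst lower triangle), the
#' AMOVA table(s), and any trees as Newick. Empty results give header-only
#' files.
#'
#' @param results Named list as returned by [run_pipeline()].
#' @param out_dir Output directory.
#' @return Invisibly, the files written.
#' @export
export_tables <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) abort(paste0("cannot create ", out_dir))
  }
  files <- c()
  files <- c(files, write_or_header(
    results$gene_diversity %||%
      tibble(gene = character(), contig_id = character()),
    file.path(out_dir, "gene_diversity.tsv")))
  files <- c(files, write_or_header(
    results$snp_classification %||% tibble(locus_id = character()),
    file.path(out_dir, "snp_classification.tsv")))
  files <- c(files, write_or_header(
    results$subpop_diversity %||% tibble(group = character()),
    file.path(out_dir, "subpop_diversity.tsv")))

  # pairwise: Nei upper, Fst lower
  pw_path <- file.path(out_dir, "pairwise_differentiation.csv")
  if (!is.null(results$pairwise)) {
    m <- results$pairwise$nei
    m[lower.tri(m)] <- results$pairwise$fst[lower.tri(m)]
    diag(m) <- 0
    utils::write.csv(as.data.frame(m), pw_path)
  } else {
    utils::write.csv(data.frame(), pw_path)
  }
  files <- c(files, pw_path)

  amova_tbl <- if (!is.null(results$amova)) {
    purrr::imap_dfr(results$amova, function(a, nm) {
      tidy(a) |> mutate(grouping = nm, .before = 1)
    }) |>
      rename(Source = "label", `Est.Var` = "est_var", `%` = "pct")
  } else {
    tibble(grouping = character(), Source = character(), df = integer(),
           SS = double(), MS = double(), `Est.Var` = double(),
           `%` = double())
  }
  files <- c(files, write_or_header(amova_tbl, file.path(out_dir, "amova.tsv")))

  if (!is.null(results$tree)) {
    writeLines(results$tree$newick, file.path(out_dir, "tree.nwk"))
    files <- c(files, file.path(out_dir, "tree.nwk"))
  }
  if (!is.null(results$membership)) {
    files <- c(files, write_or_header(results$membership,
                                      file.path(out_dir, "membership.tsv")))
  }
  if (!is.null(results$filter_report)) {
    files <- c(files, write_or_header(results$filter_report,
                                      file.path(out_dir, "filter_report.tsv")))
  }
  invisible(files)
}
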