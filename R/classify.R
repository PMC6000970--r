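#' Conservative vs non-conservative amino-acid substitution
#'
#' Operationalizes "does the substitution change the physicochemical
#' character of the residue" with a substitution-matrix rule: a pair scoring
#' at least `threshold` in BLOSUM62 (default +1) is `conservative`, anything
#' at or below zero is `non_conservative`. Identical residues are always
#' conservative. Score-0 pairs (F/L, A/T, N/K, S/G, ...) are
#' non-conservative; score +1 pairs (K/E, R/Q, N/S, V/L, ...) conservative.
#'
#' @param aa_wild,aa_mutant Character vectors of single-letter amino acids.
#' @param matrix Substitution matrix (defaults to BLOSUM62 from Biostrings).
#' @param threshold Minimum score called conservative (default 1).
#' @return Character vector: `conservative` / `non_conservative`.
#' @examples
#' conservation_class(c("S", "V"), c("Y", "I"))
#' @export
conservation_class <- function(aa_wild, aa_mutant, matrix = NULL,
                               threshold = 1) {
  if (is.null(matrix)) matrix <- blosum62()
  aa_wild <- toupper(aa_wild); aa_mutant <- toupper(aa_mutant)
  std <- rownames(matrix)
  if (!all(aa_wild %in% std) || !all(aa_mutant %in% std)) {
    abort("nonstandard amino-acid symbol")
  }
  score <- matrix[cbind(aa_wild, aa_mutant)]
  ifelse(aa_wild == aa_mutant | score >= threshold,
         "conservative", "non_conservative")
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  aa <- intersect(rownames(m), strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  m[aa, aa]
}

#' Coding effect of a SNP within its codon
#'
#' Translates the reference codon and each single-base mutant codon with the
#' standard genetic code. The effect is `synonymous` only when every mutant
#' amino acid equals the reference amino acid.
#'
#' @param ref_codon Reference codon (3 bases, coding strand).
#' @param offset 0-based position of the SNP within the codon (0-2), on the
#'   coding strand.
#' @param alt_bases Character vector of alternate bases as reported on the
#'   reference (forward) strand.
#' @param strand `"+"` or `"-"`; on `"-"` the alternate bases are
#'   complemented before substitution.
#' @return List with `effect`, `aa_ref`, `aa_alts`.
#' @examples
#' coding_effect("GGT", 2, "C")   # Gly -> Gly, synonymous
#' @export
coding_effect <- function(ref_codon, offset, alt_bases, strand = "+") {
  if (is.na(offset)) abort("codon offset (frame) missing for exonic locus")
  ref_codon <- toupper(ref_codon)
  stopifnot(nchar(ref_codon) == 3, offset %in% 0:2)
  alt <- toupper(alt_bases)
  if (strand == "-") alt <- chartr("ACGT", "TGCA", alt)
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[ref_codon])
  aa_alts <- map_chr(alt, function(b) {
    codon <- ref_codon
    substr(codon, offset + 1, offset + 1) <- b
    unname(code[codon])
  })
  effect <- if (all(aa_alts == aa_ref)) "synonymous" else "nonsynonymous"
  list(effect = effect, aa_ref = aa_ref, aa_alts = aa_alts)
}

#' Assign the wild-type (likely ancestral) allele at a SNP
#'
#' The outgroup allele is taken as wild-type when it matches one of the
#' observed alleles; otherwise (outgroup missing or unobserved among the
#' panel's alleles) the most frequent allele in the panel is used. An exact
#' frequency tie with an uninformative outgroup resolves to the reference
#' allele and is flagged.
#'
#' @param alleles Character vector of observed alleles, reference first.
#' @param freqs Numeric vector of panel frequencies, parallel to `alleles`.
#' @param outgroup Outgroup allele (single base) or `NA`.
#' @return List with `wild_type_allele`, `source` (`outgroup` / `majority`),
#'   `wildtype_freq`, `tie` flag.
#' @export
assign_wild_type <- function(alleles, freqs, outgroup = NA) {
  stopifnot(length(alleles) == length(freqs), length(alleles) >= 2)
  if (!is.na(outgroup) && toupper(outgroup) %in% toupper(alleles)) {
    i <- match(toupper(outgroup), toupper(alleles))
    return(list(wild_type_allele = alleles[i], source = "outgroup",
                wildtype_freq = freqs[i], tie = FALSE))
  }
  mx <- max(freqs)
  tie <- sum(freqs == mx) > 1
  i <- if (tie) 1L else which.max(freqs)  # reference allele is listed first
  list(wild_type_allele = alleles[i], source = "majority",
       wildtype_freq = freqs[i], tie = tie)
}

#' Frequency class of the wild-type allele
#'
#' Partitions `[0, 1]` completely and disjointly: frequencies at or below
#' 0.25 or at or above 0.75 are `rare` (the minor variant is rare), the
#' 0.40-0.60 band inclusive is `balanced`, and the two remaining open
#' intervals are `common`.
#'
#' @param wildtype_freq Numeric vector in `[0, 1]`.
#' @return Character vector: `rare` / `common` / `balanced`.
#' @export
frequency_class <- function(wildtype_freq) {
  x <- wildtype_freq
  if (any(is.na(x)) || any(x < 0 | x > 1)) abort("frequencies must be in [0, 1]")
  dplyr::case_when(
    x <= 0.25 | x >= 0.75 ~ "rare",
    x >= 0.40 & x <= 0.60 ~ "balanced",
    TRUE ~ "common"
  )
}

#' Subpopulation prevalence of a SNP allele
#'
#' An allele is `prevalent` in a subpopulation when it occurs only there, or
#' when its frequency is at least 0.75 there and below 0.25 in every other
#' subpopulation. It is `diagnostic` when its frequency is at least 0.50
#' there and below 0.05 everywhere else. A SNP meeting both definitions is
#' reported as diagnostic.
#'
#' @param freqs Named numeric vector: allele frequency per subpopulation.
#' @return Tibble with `subpopulation` and `status`
#'   (`prevalent` / `diagnostic` / `none`).
#' @export
subpopulation_prevalence <- function(freqs) {
  if (length(freqs) < 2) abort("need at least two subpopulations")
  if (is.null(names(freqs))) names(freqs) <- paste0("P", seq_along(freqs))
  status <- map_chr(seq_along(freqs), function(i) {
    f <- freqs[i]; oth <- freqs[-i]
    diagnostic <- !is.na(f) && f >= 0.50 && all(oth < 0.05, na.rm = TRUE)
    prevalent <- !is.na(f) &&
      ((f > 0 && all(oth == 0, na.rm = TRUE)) ||
         (f >= 0.75 && all(oth < 0.25, na.rm = TRUE)))
    if (diagnostic) "diagnostic" else if (prevalent) "prevalent" else "none"
  })
  tibble(subpopulation = names(freqs), status = status)
}

#' Ecotype predominance of a SNP's mutant allele
#'
#' Two-proportion chi-square test (no continuity correction, `alpha` = 0.05)
#' on mutant-allele counts in upland vs lowland genotypes.
#'
#' @param k_upland,n_upland Mutant-allele count and total allele count in
#'   upland genotypes.
#' @param k_lowland,n_lowland Same for lowland genotypes.
#' @param alpha Significance level.
#' @return One of `upland_predominant`, `lowland_predominant`, `shared`.
#' @export
ecotype_class <- function(k_upland, n_upland, k_lowland, n_lowland,
                          alpha = 0.05) {
  if (n_upland == 0 || n_lowland == 0) {
    warn("an ecotype has zero called genotypes; returning 'shared'")
    return("shared")
  }
  p <- suppressWarnings(
    stats::prop.test(c(k_upland, k_lowland), c(n_upland, n_lowland),
                     correct = FALSE)$p.value)
  if (is.na(p) || p > alpha) return("shared")
  if (k_upland / n_upland > k_lowland / n_lowland) "upland_predominant"
  else "lowland_predominant"
}

split_alts <- function(alt_alleles) {
  strsplit(gsub(" ", "", alt_alleles), ",")
}

# Per-allele panel frequencies for one locus: the summed non-reference dosage
# is split between alt1/alt2 by their read-fraction share.
locus_allele_freqs <- function(dataset, j, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(dataset$samples))
  d <- dosage(dataset)[idx, j]
  q <- mean(d, na.rm = TRUE)
  if (is.nan(q)) q <- NA_real_
  alts <- split_alts(dataset$loci$alt_alleles[j])[[1]]
  if (length(alts) == 1 || is.null(dataset$alt2_fraction)) {
    share2 <- 0
  } else {
    af <- dataset$alt_fraction[idx, j]; a2 <- dataset$alt2_fraction[idx, j]
    w <- dataset$depth[idx, j]
    tot <- sum(af * w, na.rm = TRUE)
    share2 <- if (tot > 0) sum(a2 * w, na.rm = TRUE) / tot else 0
  }
  freqs <- c(1 - q, q * (1 - share2), if (length(alts) > 1) q * share2)
  setNames(freqs, c(dataset$loci$ref_allele[j], alts))
}

#' Classify every retained SNP
#'
#' Runs the full per-SNP annotation: coding effect and amino acids for
#' exonic loci (from the reference contig sequences), conservation class of
#' the highest-frequency mutant, wild-type allele and source, frequency
#' class, subpopulation prevalence of the non-wild-type allele, and ecotype
#' predominance.
#'
#' @param dataset A filtered [snp_dataset()].
#' @param reference Named character vector or `Biostrings::DNAStringSet` of
#'   contig sequences (needed for coding effects; optional otherwise).
#' @param subpop Optional per-sample subpopulation labels (defaults to no
#'   prevalence columns).
#' @return Tibble with one row per SNP.
#' @export
classify_snps <- function(dataset, reference = NULL, subpop = NULL) {
  stopifnot(inherits(dataset, "snp_dataset"))
  loci <- dataset$loci
  ref_seqs <- NULL
  if (!is.null(reference)) {
    ref_seqs <- if (inherits(reference, "DNAStringSet"))
      setNames(as.character(reference), names(reference)) else reference
  }
  eco <- dataset$samples$ecotype
  d <- dosage(dataset)

  rows <- map(seq_len(nrow(loci)), function(j) {
    lc <- loci[j, ]
    freqs <- locus_allele_freqs(dataset, j)
    wt <- assign_wild_type(names(freqs), unname(freqs), lc$outgroup_allele)
    mut <- freqs[setdiff(names(freqs), wt$wild_type_allele)]
    mut <- mut[order(-mut)]

    effect <- "noncoding"; aa_wild <- NA_character_
    aa_mutants <- NA_character_; conservation <- "n/a"
    if (identical(lc$region, "exon") && !is.null(ref_seqs) &&
        lc$contig_id %in% names(ref_seqs)) {
      strand <- if ("strand" %in% names(lc) && !is.na(lc$strand)) lc$strand else "+"
      ctx <- codon_context(ref_seqs[[lc$contig_id]], lc$position,
                           lc$codon_frame, strand)
      alts <- split_alts(lc$alt_alleles)[[1]]
      ce <- coding_effect(ctx$codon, ctx$offset, alts, strand)
      effect <- ce$effect
      aa_by_allele <- setNames(c(ce$aa_ref, ce$aa_alts), c(lc$ref_allele, alts))
      aa_wild <- unname(aa_by_allele[wt$wild_type_allele])
      aa_mut <- aa_by_allele[names(mut)]
      aa_mutants <- paste(aa_mut, collapse = ",")
      if (effect == "nonsynonymous" && length(aa_mut)) {
        top <- unname(aa_mut[1])
        conservation <- if (is.na(aa_wild) || is.na(top)) {
          "n/a"
        } else if (aa_wild == "*" || top == "*") {
          "non_conservative"  # stop gain/loss always changes the protein
        } else {
          conservation_class(aa_wild, top)
        }
      }
    }

    mut_freq_total <- sum(mut)
    prev <- NULL
    if (!is.null(subpop)) {
      sub_freqs <- map_dbl(split(seq_len(nrow(d)), subpop), function(idx) {
        f <- locus_allele_freqs(dataset, j, idx)
        sum(f[setdiff(names(f), wt$wild_type_allele)])
      })
      pv <- subpopulation_prevalence(sub_freqs)
      prev <- paste(pv$subpopulation[pv$status != "none"],
                    pv$status[pv$status != "none"],
                    sep = ":", collapse = ";")
      if (prev == "") prev <- "none"
    }

    is_up <- eco == "upland"; is_low <- eco == "lowland"
    n_up <- 2 * sum(!is.na(d[is_up, j])); n_low <- 2 * sum(!is.na(d[is_low, j]))
    k_up <- round(2 * sum(d[is_up, j], na.rm = TRUE))
    k_low <- round(2 * sum(d[is_low, j], na.rm = TRUE))
    eclass <- if (n_up > 0 && n_low > 0)
      ecotype_class(k_up, n_up, k_low, n_low) else "shared"

    tibble(
      locus_id = lc$locus_id, gene = lc$gene, contig_id = lc$contig_id,
      chromosome = lc$chromosome, subgenome = lc$subgenome,
      position = lc$position, region = lc$region,
      effect = effect, aa_wild = aa_wild, aa_mutants = aa_mutants,
      conservation = conservation,
      wild_type_allele = wt$wild_type_allele, wild_type_source = wt$source,
      wildtype_freq = wt$wildtype_freq,
      mutant_alleles = paste(names(mut), collapse = ","),
      mutant_freqs = paste(sprintf("%.4f", unname(mut)), collapse = ","),
      frequency_class = frequency_class(min(max(wt$wildtype_freq, 0), 1)),
      prevalence = prev %||% NA_character_,
      ecotype_class = eclass
    )
  })
  bind_rows(rows)
}

codon_context <- function(seq, position, frame, strand = "+") {
  if (is.na(frame)) abort("codon frame missing for exonic locus")
  if (strand == "+") {
    start <- position - frame
    codon <- substr(seq, start, start + 2)
    list(codon = toupper(codon), offset = frame)
  } else {
    # frame counts within the codon read on the coding (minus) strand
    endq <- position + frame
    codon_fwd <- substr(seq, endq - 2, endq)
    codon <- chartr("ACGT", "TGCA",
                    paste(rev(strsplit(toupper(codon_fwd), "")[[1]]),
                          collapse = ""))
    list(codon = codon, offset = frame)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
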