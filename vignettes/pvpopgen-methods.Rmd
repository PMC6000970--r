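---
title: "Methods: candidate-gene amplicon population genetics in pvpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene amplicon population genetics in pvpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pvpopgen analyses candidate-gene amplicon SNP panels in allotetraploid
switchgrass (*Panicum virgatum*), where each gene exists as two homoeologous
copies on the K and N subgenomes and amplicons are mapped per copy, so each
contig behaves as an independent disomic (diploid) locus set. This vignette
explains the models and procedures, the parameters that matter, and the
choices made where the design was genuinely open.

## Zygosity calling and filtering

Genotypes are called from per-sample read fractions rather than taken from an
upstream caller. With a disomic genotype the alternate-read fraction is
expected near 0, 0.5 or 1; the calling windows are:

* fraction < 0.25 → homozygous reference, > 0.75 → homozygous alternate;
* fraction in [0.40, 0.60] → heterozygous;
* the gaps [0.25, 0.40) and (0.60, 0.75] fit neither expectation and are
  called *ambiguous*. Ambiguous calls are treated as missing in every
  downstream allele-frequency computation — the bands are deliberately
  conservative, and in deep amplicon data almost all fractions fall well
  inside the homozygous or heterozygous windows.

The boundary policy (0.25/0.75 excluded from homozygous, 0.40/0.60 included
in heterozygous) follows the strict inequalities of the calling rule.

Site filters run in a fixed, logged order so the removal tallies are
reproducible: INDELs → adjacency → depth masking → site missingness → MAF.
Runs of variants at immediately adjacent positions are alignment artefacts at
amplicon scale and the *whole run* is removed, not just the later member.
Calls below 3 reads are masked to missing *before* missingness and frequency
are evaluated, so the population allele frequency (mean alt dosage over
called genotypes; hom = 0/1, het = 0.5) never rests on unreliable calls.
Sites with ≥ 20% missing calls, and then sites with population alternate
frequency outside [0.05, 0.95], are dropped; finally samples with > 30%
missing calls are discarded. Each removed variant is counted in exactly one
report category (the first rule that removes it), and filtering is
idempotent.

## SNP classification

**Coding effect.** Exonic SNPs are placed in their codon using the annotated
frame and strand and translated with the standard genetic code; a SNP is
synonymous only if *every* alternate amino acid equals the reference amino
acid. Stop gains/losses are treated as non-conservative outright.

**Conservation.** "Does the substitution change the residue's
physicochemical character" is operationalized with a substitution-matrix
rule: BLOSUM62 score ≥ +1 → conservative, ≤ 0 → non-conservative, identity
always conservative. The threshold at +1 is the empirically coherent cut:
score-0 pairs such as F/L, A/T, N/K and S/G all behave as property-changing
substitutions in the curated example table, while +1 pairs such as K/E, R/Q,
N/S and V/L behave as conservative. Both the matrix and the threshold are
configurable; the shipped rule reproduces all 49 curated labels
(32 non-conservative, 17 conservative).

**Wild-type allele.** The allele matching the outgroup (*Setaria*-like)
state is taken as ancestral; when the outgroup is missing or matches no
observed allele, the panel-majority allele is used. An exact 50/50 tie with
an uninformative outgroup resolves to the reference allele and is flagged.

**Frequency class.** Classes partition [0, 1] completely by the wild-type
frequency: ≤ 0.25 or ≥ 0.75 rare; [0.40, 0.60] balanced; the two remaining
open intervals common.

**Prevalence.** A SNP allele is *prevalent* in a subpopulation when it
occurs only there, or at frequency ≥ 0.75 there and < 0.25 everywhere else;
*diagnostic* when ≥ 0.50 there and < 0.05 everywhere else; a SNP meeting
both is reported diagnostic (the stronger statement). Triallelic sites use
the highest-frequency mutant for row-level labels; the per-allele frequency
split is recovered from the read-fraction shares.

**Ecotype predominance.** No test is prescribed for "predominantly present
in one ecotype", so a two-proportion chi-square test (no continuity
correction, α = 0.05) on mutant-allele counts is used and documented; at the
planted effect size (0.8 vs 0.05, 100 genotypes per ecotype) sensitivity
exceeds 95%.

## Diversity and neutrality

Per-locus indices are the classical codominant set (He, Ho, Ne, Shannon I,
F = 1 − Ho/He), with group summaries reporting %P, private-allele counts and
means with standard errors over loci.

**Phasing.** Haplotypes over each contig's SNPs are reconstructed by
Excoffier–Slatkin EM: all haplotype pairs compatible with each genotype are
enumerated, expected haplotype counts are iterated to convergence
(log-likelihood change < 1e-6), and each sample is resolved to its most
probable pair. A coalescent-informed Gibbs phaser would add accuracy only
for long, sparse haplotypes; at amplicon scale (tens of SNPs, few
heterozygous sites per individual) EM is statistically adequate and fully
deterministic, which we prefer for reproducible tables. The enumeration is
capped at 16 heterozygous sites per individual; missing genotypes are
imputed to the locus major-allele homozygote before phasing so every sample
contributes exactly two haplotypes (the imputed count is reported). One
uniform start plus three random restarts guard against local optima; the EM
log-likelihood is non-decreasing by construction and tested as such.

**Sequence statistics.** π is the per-site heterozygosity form with the
n/(n−1) bias factor; Watterson's θ is S/(a₁L); their standard deviations use
the standard neutral-theory variance formulas, and haplotype diversity is
Hd = n/(n−1)(1 − Σf²). SNP density is d = 100·S/L exactly. Tajima's D uses
the standard constants; Fu & Li's statistic defaults to F\* (sample
singletons) and switches to F (derived singletons) whenever outgroup states
cover all segregating sites — the variant used is recorded in the output.
Under 1000 neutral coalescent replicates (n = 20, θ = 5) the mean D sits
within ±0.15 of zero and π and θ agree within 5%.

## Differentiation and AMOVA

Gst is Nei's (Ht − Hs)/Ht with Ht from pooled mean frequencies and both
terms averaged over loci before the ratio; significance comes from permuting
individuals across groups (999 by default). Pairwise Fst is pair-restricted
Nei Gst — the tool the layout mirrors does not document its pairwise
estimator, so the transparent choice is labeled and a Weir–Cockerham option
provided. Nei's standard distance caps at 10 (flagged) when no alleles are
shared. Gene flow is Nm = 0.5(1 − Gst)/Gst.

The AMOVA is the three-level codominant partition (among groups / among
individuals within groups / within individuals) on squared Euclidean
distances between gametic 0/1 vectors; the heterozygote split between
gametes is arbitrary but distances are invariant to it. Missing loci are
excluded pairwise and distances rescaled to the full locus count. Variance
components come from the nested mean squares (the gametes-per-individual
coefficient is exactly 2; the among-group coefficient handles unbalanced
groups), are truncated at zero, and are reported with integer percentages.
Among-group significance permutes whole individuals among groups; Phi_IS
permutes gametes among individuals within groups. Groups of size one cannot
support a within-group term and are merged into a shared residual group with
a warning.

## Structure, K selection and PCoA

The admixture model is fit by a Gibbs sampler (Rcpp): each allele copy
carries a latent cluster of origin drawn from the individual's ancestry
vector q ~ Dirichlet(α), cluster allele frequencies have independent
uniform priors, and the sampler alternates P | z, q | z and z | q,P updates.
LnP(D) is estimated as mean(lnL) − var(lnL)/2 over post-burn-in iterations.
Full protocol defaults are 100k burn-in / 100k iterations and 10 runs over
K = 1..10; the packaged tests use 1k/2k, which is sufficient for the planted
fixtures (Q-RMSE < 0.1 against truth at K = 3). α defaults to 1.

The protocol this mirrors reports "the run with the lowest likelihood",
which conflicts with standard best-run practice and is most likely a typo;
both behaviours are supported (`run_selection = "highest"` is the default).
K is chosen by the ad hoc LnP(D) criterion with plateau detection: the
smallest K whose mean LnP(D) lies within one run-level standard deviation of
the maximum. Membership follows the 70% rule (argmax cluster; max q < 0.70 →
admixed), and an accession is representative of a subpopulation when > 70%
of its genotypes are assigned there.

PCoA double-centres the same squared-dosage distance the AMOVA uses, for
internal consistency; variance percentages are taken over positive
eigenvalues only.

## Spatial and phylogeographic analyses

Geographic distance is great-circle (haversine) in km. The Mantel test
correlates off-diagonal entries with joint row/column permutation (via
vegan); the literature is silent on log-transforming geographic distance, so
linear is the default with a `log_b` option. The 2D-LSA statistic is each
individual's mean genetic similarity (1 − d/d_max over the panel) to its n
nearest geographic neighbors, with a one-tailed permutation test (genotypes
permuted over locations, 9999 permutations at protocol scale) swept over
n = 7..14; an individual is *consistently* significant only if p ≤ 0.05 at
every sweep value. Duplicate coordinates break ties by sample order, with a
warning.

Trees are UPGMA on genotype p-distance: the mean per-site dosage
difference, which scores a heterozygote against either homozygote as 0.5 —
exactly the expected mismatch of randomly drawn alleles, i.e. fractional
IUPAC ambiguity matching on the concatenated genotype sequence. A TN93
option covers the composite-likelihood convention when nucleotide sequences
are supplied. Support comes from bootstrapping SNP columns (500 replicates
at protocol scale); trees are ultrametric by construction and tested to
1e-9.

Divergence dating is linear calibration: t = 13 Mya × (between-group
distance)/(ingroup-to-outgroup distance). It is scale-invariant, so it can
be applied to SNP-only distances for *relative* statements; the packaged
subgenome dating instead uses full consensus contig sequences against
matched outgroup sequences, where the ratio is an absolute estimate
(defaults emulate a K/N split near 5.7 Mya against the 13 Mya calibration).

## Subgenome contrasts

SNP counts are profiled in non-overlapping 100-bp windows anchored at
position 1 of the analyzed region. Per-gene K-vs-N contrasts use only genes
with both homoeologs and with called data in > 80% of accessions; when
analyzed-region lengths are supplied the contrast is SNP density over the
shared region. Homoeolog pairing comes from the annotation — no sequence
alignment between homoeologs is attempted, since contig pairing is input
metadata in this design.

## The synthetic data generator

`simulate_dataset()` emits a complete panel plus its ground truth. Defaults
emulate the target study design: 36 accessions × 10 genotypes (360 samples),
3 genetic subpopulations at Balding–Nichols F = 0.2 from Uniform(0.05, 0.95)
ancestral frequencies, 12 genes of which 9 are homoeolog pairs (21 contigs
of 2.4 kb), ~12 SNPs per contig (~250 SNPs, ~6% triallelic), ancestry
shaped by geographic proximity to subpopulation anchor points (producing
isolation-by-distance and a latitude-linked ecotype gradient), disomic
genotypes drawn independently per subgenome contig, Poisson read depths with
binomial allele fractions (1% read error), 5% dropout, and outgroup
divergence of 0.05 substitutions/site with a 2.2% K/N homoeolog divergence.

Mean SNP-site depth defaults to 30 reads. Raw genome-wide coverage averages
in amplicon studies are much lower because they include unenriched regions,
but retained amplicon SNP sites carry on the order of 100× coverage; at a
mean depth below ~10 the binomial fraction of a true heterozygote falls
outside the [0.40, 0.60] window so often that the calling rule would label
most heterozygotes ambiguous, which real deep amplicon data does not show.

The generator does **not** emulate: coalescent gene genealogies or
recombination within contigs (sites are exchangeable given subpopulation
frequencies), mapping or paralog-collapse artefacts, base-quality error
structure, or octoploid segregation (ploidy is metadata only; all
inheritance is disomic per subgenome). Tests passing on these panels
therefore validate the estimators and bookkeeping, not robustness to
misalignment or to polysomic inheritance.

## Numerical choices and problem sizes

EM convergence tolerance 1e-6 (log-likelihood units); Nei-distance cap 10;
permutation p-values use the (1 + #{perm ≥ obs})/(n_perm + 1) convention;
wild-type frequency ties resolve to the reference allele with a flag; all
seeds flow from a single configuration seed (per-K fits offset the seed so
runs are independent but reproducible). The test suite runs the full
pipeline on the default 360 × ~250 panel with 1k/2k MCMC at K = 3, 99
permutations and 20 bootstrap replicates; property suites use 1000 neutral
coalescent replicates (n = 20, θ = 5), 200-locus Balding–Nichols panels with
100 individuals per group, and a 150-locus, 3 × 40 planted admixture
fixture. Protocol-scale settings (100k MCMC, 10 runs, K ≤ 10, 9999 LSA
permutations, 500 bootstraps) remain the configuration defaults.

## Known limitations

Pairwise Fst/Nei values depend on the estimator convention and are not
comparable across tools without checking that convention. Subpopulation
divergence dates from SNP-only matrices are relative, not absolute. The
admixture sampler uses the independent-frequency prior only (no correlated
frequencies, no CLUMPP-style multi-run averaging). PHASE-style
coalescent-informed phasing, πN/πS rate ratios, sliding windows along
chromosomes and de novo homoeolog assignment are out of scope.
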