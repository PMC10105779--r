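---
title: "Methods: scoring calcification groups across omics layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring calcification groups across omics layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcomics)
```

# Scope and model

`calcomics` implements the per-sample scores and cohort statistics used to
contrast triple-negative breast cancers (TNBC) carrying mammographic
calcifications of high suspicion for malignancy (BI-RADS 4C--5) against
tumors with probably benign calcifications (BI-RADS 2--3), low--moderate
suspicion (4A--4B), or no calcifications. Samples carry one of four closed
group labels (`calcGroups()`); the primary contrast is high suspicion
versus everything else, with high-suspicion-vs-probably-benign and
high-suspicion-vs-negative as the pairwise alternatives.

The package assumes its inputs are *processed* omics tables: a MAF-like
somatic mutation catalog, ASCAT-style allele-specific copy-number
segments, a log2 expression matrix, and log2 metabolite/lipid matrices
with annotation sidecars. Raw-data processing (variant calling, array
segmentation, LC--MS identification) is out of scope, as are HLA typing
and peptide--MHC affinity prediction, whose outputs are consumed as
inputs.

# Genome-instability scores

**Tumor mutation burden.** Nonsynonymous mutations (missense, nonsense,
nonstop, splice site, translation start site, in-frame and frameshift
indels) per megabase of captured coding exome. The default footprint is
35.618 Mb, the coding footprint of the exome capture kit behind the
default analysis; it is a plain argument for other kits.

**HRD scar score.** The sum of three components computed from
allele-specific segments with `nMajor >= nMinor` enforced on ingest:

* *NtAI*: maximal runs of allelic imbalance (`nMajor != nMinor`) that
  touch exactly one telomere, are longer than 11 Mb, and do not span the
  whole chromosome. "Longer than" is read strictly here and in the other
  two components. Whether pure LOH counts as imbalance is configurable
  (`includeLoh`, default yes, the standard NtAI convention).
* *LOH*: maximal runs with `nMinor == 0`, `nMajor > 0`, longer than 15 Mb
  but shorter than the whole chromosome, with chromosome 17 excluded by
  default.
* *LST*: breakpoints whose two flanking regions each exceed 10 Mb after
  smoothing. Smoothing first merges identical adjacent states, then
  repeatedly deletes the leftmost region shorter than 3 Mb, closing the
  gap by extending the left neighbor (the right neighbor at a chromosome
  start) and re-merging. Merging-before-deletion makes all three scores
  invariant under segment subdivision, which the test suite checks by
  property. When the genome build carries centromeres, breakpoints are
  counted per chromosome arm (segments are cut at the centromere
  midpoint), the convention of the original LST literature; a
  whole-chromosome mode is available for builds without a centromere
  model and both modes are exposed (`armAware`).

Telomere contact is defined against the covered extent of each
chromosome: a run is telomeric when it contains the first or the last
covered segment. This is exact for fully tiled synthetic profiles and a
reasonable proxy for real segmentations, which rarely reach the assembly
ends.

**HLA-I status.** Germline homogeneity means two identical 4-digit
alleles at any of HLA-A/B/C. Tumor HLA-I LOH is called when any segment
overlapping any HLA-I locus has zero minor-allele copies; when every
locus is covered and none shows LOH the sample is non-LOH; an uncovered
locus without LOH elsewhere yields `indeterminate` rather than a guess.
Locus coordinates are an argument; the package ships toy loci on the
synthetic genome.

**Clustered mutations.** A sample-specific inter-mutational distance
(IMD) threshold is calibrated against 100 background simulations that
re-place the sample's per-chromosome mutation counts uniformly. A
candidate threshold (each observed nearest-neighbor IMD) qualifies when
at least 90% of the real mutations below it are in excess of the
simulated expectation and the BH-adjusted simulation p-value is below
0.1; the largest qualifying threshold wins. The uniform background is a
deliberate desk-scale simplification of context-preserving mutation
shuffling; it preserves the counts and the chromosome structure but not
the trinucleotide context of the background. Clusters (maximal runs of
consecutive IMDs at or below the threshold, never across chromosomes)
are subclassified: `DBS` (two mutations, adjacent positions), `MBS`
(three or more, all adjacent), `omikli` (two or three with an IMD above
1 bp) and `kataegis` (four or more with an IMD above 1 bp). The
four-mutation cut for kataegis follows the clustered-mutation
literature's distinction between diffuse and longer events and is
configurable in spirit: the classifier takes the threshold as an
argument, so any calibration can be substituted.

**SBS96 and refitting.** SNVs are binned into the canonical 96
pyrimidine-strand trinucleotide classes; purine-reference records are
reverse-complemented first, and a catalog always sums to its number of
contributing SNVs. Refitting solves a non-negative least-squares problem
per sample against a fixed reference signature matrix (rows summing
to 1). The optional sparsity pass greedily removes the lowest-exposure
signature while the cosine similarity between catalog and reconstruction
stays within 0.01 of the full fit -- a documented, deterministic
stand-in for the unspecified penalization of single-sample refitting
tools; the cumulative (rather than stepwise) cosine budget bounds the
total reconstruction loss of the pass.

**Neoantigen filter.** Candidates with precomputed binding predictions
pass when affinity < 500 nM *and* expression > 1, both strict, matching
the stated definition; candidates lacking an affinity are skipped with a
warning rather than silently dropped.

# Transcriptome scoring

**Literature-signature scores** follow the three-step recipe: mean-center
each gene across samples, average over the signature genes per sample,
z-score across the cohort. Scores are therefore exactly standardized and
invariant to per-gene additive offsets; the single-gene case collapses
to the z-scored gene, which the tests exploit as an oracle.

**ssGSEA.** Per sample, features are ranked with average-rank ties and
walked in decreasing rank order (ties broken deterministically by row
index); in-set features add `rank^0.25` normalized over the set,
out-of-set features subtract a uniform step, and the enrichment score is
the sum of the running statistic. The 0.25 exponent and the cross-cohort
min--max normalization are defaults in the spirit of the common ssGSEA
implementation, both configurable; scores depend only on ranks, so any
monotone per-sample transform leaves them unchanged. TME inference is
ssGSEA over a cell-type marker compendium (e.g. 24 cell types); the
package does not ship the proprietary compendium and accepts any GMT.

**Subtyping.** mRNA subtype uses k-means (k = 4 by default) on the genes
with the top 2000 SDs; immune subtype scales each cell-type score and
clusters with a caller-chosen k. Multi-index cluster-number votes are
replaced by a transparent silhouette scan (`silhouetteScan()`), since a
30-index voting machine adds dependency weight without changing the
decision the caller must make. Subtype labels are cluster indices;
biological names (LAR/IM/BLIS/MES, immunomodulatory/inflamed/excluded/
desert) require external marker knowledge and are attached by the
caller, never hard-coded.

# Metabolome

**Prefiltering** keeps features with tumor-vs-normal BH FDR < 0.01 and
|log2 FC| > 1 (both strict), then truncates to the top-SD features (200
metabolites, 400 lipids in the study design). Matrices are expected on
the log2 scale, so the fold change is a difference of group means.

**DA score.** Per metabolite, a two-sided Mann--Whitney U test at raw
alpha 0.05 and a direction from the median difference; per pathway with
at least three profiled metabolites, DA = (increased − decreased) /
measured, bounded in [−1, 1] with the endpoints meaning "all profiled
metabolites up" / "all down". Raw (unadjusted) per-metabolite p-values
are the convention of the DA-score methodology; alpha and the adjustment
are arguments for stricter uses. The median-based direction matches the
rank-based test; a mean-based direction could disagree with the test on
skewed features.

**Lipid subclass fold changes** are computed per lipid and summarized
per subclass (median, IQR). Both fold-change conventions are
implemented -- log2 ratio of group means for linear-scale data (default)
and difference of means for log2-scale data -- because the convention is
genuinely ambiguous in the field; the pipeline uses the log2-difference
form since its matrices are log2.

**SNF.** Each layer yields a scaled-exponential-kernel affinity
(`exp(-d^2 / (alpha * mu))` with a local scale `mu` averaging
K-nearest-neighbor distances); full kernels are cross-diffused through
the other layers' kNN kernels for 20 iterations and averaged. K = 20,
alpha = 0.5 and T = 20 are the canonical SNF defaults. Cross-diffusion
intentionally smooths fine within-cluster detail while sharpening the
cluster structure; the tests therefore check neighborhood-rank
preservation and block contrast rather than elementwise equality.
Metabolite subtypes come from normalized spectral clustering of the
fused network at k = 3, the cluster number the study design fixes.

# Cohort statistics

Binary features are contrasted by binomial-family logistic regression
(odds ratio, Wald CI), falling back to Fisher's exact test on zero cells
or separation with the fallback flagged; the unadjusted two-group OR
equals the 2x2 cross-product ratio, which the tests use as a closed-form
oracle. Continuous features use a gaussian-family linear model for the
estimate and CI with a Wilcoxon rank p-value alongside. Gene-level
frequency tables BH-adjust within each contrast across genes -- multiple
testing is controlled within each feature family (genes, signatures,
pathways) separately, mirroring how per-figure analyses are organized.
Survival endpoints (OS, DMFS, RFS, months since surgery) are modeled by
Cox proportional hazards adjusted by default for age, tumor size
category and nodal status; the covariate set is an argument and is
recorded verbatim in every result row and the run manifest, because the
adjusted models' covariates are a reporting decision, not something to
guess silently.

# Synthetic cohorts and what they do (not) show

`generateCohort()` draws a cohort whose defaults emulate the study
conditions: 312 samples; group proportions 0.55 / 0.22 / 0.08 / 0.15
(negative, probably benign, low--moderate, high suspicion -- per-group
sizes are not published, so the split reflects the reported 10--30%
calcification prevalence in TNBC with high-suspicion cases the smaller
part); ~56 somatic mutations per sample (median 53 SNVs + 3 indels);
PIK3CA mutation probability 29.6% in the high-suspicion group versus
~16% elsewhere; a −1 SD immune-signature shift and a +1.5 log2
lipid-pathway shift in the high-suspicion group; an OS hazard ratio
of 2 for high suspicion over an exponential baseline (0.006/month) with
uniform administrative censoring calibrated to a 30% censored fraction.
Scar events (telomeric imbalance, interior LOH runs, state-transition
blocks, HLA-region LOH) are carved into a 10 x 100 Mb synthetic genome
with centromeres at 48--52 Mb, so no reference genome ships with the
package. Mutation positions are uniform per chromosome with uniform
trinucleotide flanks; expression noise is unit-variance normal per gene
around per-gene means; metabolite/lipid noise is unit-variance normal on
the log2 scale (log-normal abundances). Every planted parameter is
recorded in the `truth` slot and a `truth.json` on disk.

These cohorts make every downstream estimator testable against known
truth, and that is all they claim. They do not reproduce linkage or
clonal structure, context-dependent mutational processes, correlated
gene modules, batch effects, or the messy overlap structure of real
multi-platform cohorts (per-layer dropout is available but defaults to
zero, since the published per-layer sample counts do not pin down their
overlap). A passing suite therefore demonstrates the *estimators* are
correct and calibrated, not that any particular biological effect exists
in real data.

# Numerical choices and problem sizes

Strict inequalities are used wherever the source wording says "longer
than", "less than" or "greater than". Rank ties use average ranks with
index-order tie-breaks so every result is deterministic. All randomness
descends from a single integer seed through a fixed splitting scheme
(`seed`, layer index), keeping derived seeds within 32-bit range.
Degenerate inputs (constant features, empty groups, all-censored
cohorts, single-mutation samples) return warnings with defined values or
informative errors rather than NA propagation.

The default verification sizes -- 200-instance oracle sweeps for the
scar/DA/BH/SBS96/NNLS equivalences, a 600-sample recovery cohort, 50
Cox replicates, 600-feature null-calibration families -- were chosen so
the whole suite verifies each claim with comfortable Monte-Carlo margins
while remaining a desk-scale run on one CPU.

# Worked example

```{r example, eval = FALSE}
spec <- cohortSpec(nSamples = 312, seed = 1)
cohort <- generateCohort(spec)
scars <- computeHrd(segments(cohort), syntheticGenomeBuild())
score <- signatureScore(expressionMatrix(cohort), immuneGenes(cohort))
da <- daScore(metaboliteMatrix(cohort), cohortTable(cohort)$calc_group,
              metaboliteAnnotation(cohort), positive = "high_suspicion")
cox <- coxHazard(cohortTable(cohort), "os", c("high_suspicion", "rest"))
```

Or end-to-end with on-disk outputs:

```{r pipeline, eval = FALSE}
runPipeline(list(seed = 1, simulate = list(nSamples = 312)), "results/run1")
```

# Known limitations

* The IMD background ignores sequence context; thresholds on real,
  context-biased hypermutation may differ from a context-preserving
  simulator's.
* The refitting sparsity rule is a stand-in for unspecified proprietary
  penalization; exposures for highly collinear reference signatures
  depend on it.
* ssGSEA normalization constants differ across published
  implementations; compare scores only within one configuration.
* The generator's independence assumptions make planted effects easier
  to detect than correlated real-world effects of equal size; power
  estimates derived from it are optimistic.
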