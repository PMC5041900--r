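---
title: "Methods: multi-region tumor methylome and mutation heterogeneity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region tumor methylome and mutation heterogeneity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ithmeth)
```

## The study design this package models

`ithmeth` analyses paired pre-/post-treatment multi-region tumor cohorts of
the kind used to study intratumoral heterogeneity (ITH) in clear cell renal
cell carcinoma under anti-angiogenic therapy: per patient, one normal tissue
sample, one pre-treatment needle biopsy, and several (default three)
spatially separated nephrectomy samples taken after treatment.  Two
molecular layers are modelled jointly:

* **Methylome** — MethylCap-seq fragment counts over predefined
  "methylation cores" (genomic intervals of potential methylation).
  Methylation is read out as a count per core per sample.
* **Mutations** — targeted panel variant calls (SNVs/indels over a 48-gene
  panel), gene-level copy number from coverage ratios, and B-allele
  frequencies at germline heterozygous SNPs for loss of heterozygosity
  (LOH).

Every stage is runnable on synthetic cohorts with recorded ground truth, so
the full pipeline is testable offline.

## The differential methylation model

Counts are modelled on the log2-CPM scale,
$x_{gi} = \log_2\!\frac{y_{gi} + 0.5}{R_i + 1} \cdot 10^6$, with $R_i$ the
library size.  Cores not annotated to a promoter (including exon 1), or
with a mean count below one fragment per core, are removed first: such loci
have essentially no power and only inflate the number of hypotheses.

After quantile normalization, a precision-weighted linear model is fitted
per core.  The weights follow the voom idea: an ordinary least-squares fit
per core yields residual standard deviations; a lowess trend of
$\sqrt{s_g}$ against the average log *count* captures the mean-variance
relation; each observation's predicted standard deviation is read off the
trend at its fitted log-count value, and its weight is that value to the
power $-4$.  Working on the log-count scale (fitted log-CPM plus the
sample's log library size) matters here: the same abundance observed in a
shallow biopsy library corresponds to a smaller count, hence more
variance, hence less weight.  Biopsy libraries are deliberately simulated
at 25–50% of the nephrectomy sizes to emulate the shallow needle-biopsy
coverage seen in practice.

The per-core variances are then shrunk by empirical Bayes: the prior
$(s_0^2, d_0)$ is estimated from the marginal moments of $\log s_g^2$ via
digamma/trigamma inversion, each core's variance becomes
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, and the moderated
$t_g$ is referred to $d_0 + d_g$ degrees of freedom.  When variances are
near-identical the trigamma inversion diverges and the code takes the
$d_0 = \infty$ branch.  The implementation is cross-checked against
`limma::lmFit`/`eBayes` in the test suite but does not call it.

**Design matrix.**  Samples are patient-matched, so the default design is
*blocked*: treatment effect plus patient fixed effects.  An unblocked
two-group design (`design_type = "grouped"`) is available.  Whether the
original analyses of such cohorts blocked on patient is typically not
reported; this choice is the principal fidelity risk when comparing
absolute FDR values, which is why both designs are exposed.

**Multiple testing.**  The analysis is supervised: Benjamini–Hochberg
adjustment is restricted to the promoter cores of the target genes
(`bh_fdr(p, restrict_to = is_target)`), with a significance threshold of
FDR < 10%.  Nephrectomy replicates enter the linear model as replicate
post-treatment observations; they are averaged only in the per-patient
category analysis below.

## Quantile normalization and ties

Classical quantile normalization replaces each column by the cross-column
means of the order statistics at each rank.  With ties there is a genuine
design choice:

* `ties = "split"` (default): tied entries receive distinct reference
  values, assigned deterministically by original row order.  This
  preserves the defining post-condition *exactly* — after normalization
  every column has the identical sorted value vector — which downstream
  steps (top-variance selection, category boundaries) rely on for
  determinism.
* `ties = "average"`: tied entries receive the mean of their tied
  reference values, as microarray-era implementations do.  Tied inputs
  then map to tied outputs, but the distributional identity across
  columns holds only approximately when tie patterns differ between
  columns.

The default favours the exact invariant; for count data ties are common at
low counts, and the split rule's within-tie ordering noise is far below
the counting noise at those counts.

## Per-patient quantile categories

For a region of interest, the quartile boundaries (25/50/75th percentiles,
type-7 linear interpolation) of all samples' normalized values define four
categories: "No to low methylation", "Low to medium", "Medium to high",
"High to very high".  A value exactly on a boundary goes to the higher
category; if all values coincide the region collapses to the lowest
category by convention.  Per patient, the pre-treatment value is the
biopsy value and the post-treatment value is the mean over nephrectomy
samples; the top two categories count as hypermethylated, and the cohort
summary is the percentage of patients hypermethylated pre and post.

## Variant filtering, sharing and drivers

Calls are excluded when genotype quality < 60, when the variant allele
frequency summed over alternate alleles is < 10%, or when the call lies
within 1 bp of a homopolymer run of at least 4 bp.  "Within 1 bp" is
interpreted as: the minimum distance from any variant-affected reference
base to any base of the run is at most 1 (0 meaning inside the run).  For
deletions the affected span is the deleted bases; for insertions it is the
anchor base.  No convention for indels is standard here; this is the
conservative reading, and a missing flanking sequence is a hard error
("context unavailable") rather than a silently retained call.

Sharing is classified per patient and variant key (chrom, pos, ref, alt):
*germline* (present in the patient's own normal), *truncal* (all tumor
samples), *private* (exactly one tumor sample), *shared* (otherwise).  A
variant is *tumor-specific* only if absent from the patient's normal and
from every normal across the cohort.  A patient without a normal sample is
classified against the cohort normal panel only and can never receive a
germline label.

Candidate drivers are called from consumed annotations (no annotator is
run): frameshift, in-frame deletion, nonsense/stop-gained, splice acceptor
and splice donor always; missense only when SIFT calls it damaging or
PolyPhen-2 at least possibly damaging.  Unknown consequence terms are an
error by default (`strict = TRUE`) so vocabulary drift is caught early.

Count comparisons use the tests such studies report: per-gene biopsy vs
nephrectomy driver counts with a two-sided Wilcoxon rank-sum test (exact by
full enumeration when both groups have at most 10 samples — valid under
ties because the enumeration conditions on the observed ranks — otherwise
normal approximation with tie correction; the two-sided p doubles the
smaller tail, capped at 1); per-patient private-mutation burden (biopsy
count vs median nephrectomy count) with an unpaired Student t test; CNV
counts pre vs post with a paired Student t test.

## LOH segmentation and the CNV caller

Published LOH/CNV callers for this design (ExomeCNV, a modified EXCAVATOR)
are not specified at the algorithm level in the literature this package
follows, and their downstream use needs only segment calls and counts.
Both are therefore implemented as documented, simpler algorithms:

* **LOH** — germline heterozygous SNPs are sites with normal-sample BAF in
  [0.4, 0.6] (inclusive), bi-allelic only.  Tumor BAFs are mirrored to
  $d_j = |b_j - 0.5|$ (phase is unobservable from unphased SNPs), each
  chromosome is split by recursive binary segmentation (maximal
  two-sample t between flanks, recursing while p < `alpha`), and segments
  with mean deviation ≥ `deviation_threshold` over ≥ `min_snps` SNPs are
  flagged LOH; adjacent flagged segments merge and segments never cross a
  chromosome.  Defaults: `min_snps = 10`, `deviation_threshold = 0.15`,
  `alpha = 0.01` — at depth 200 these recover injected shifts ≥ 0.2 with
  boundary error ≤ 5 SNP indices in ≥ 95% of runs (asserted by
  simulation).  Sub-clonal LOH never drives BAF fully to 0 or 1; mirroring
  keeps such segments detectable, and LOH features are excluded from the
  phylogenetic distance matrix by default, mirroring their likely
  sub-clonal nature.
* **CNV** — per-target coverages of tumor and normal are median-normalized,
  the per-gene mean of log2(tumor/normal) is thresholded (loss < −0.4,
  gain > +0.3 by default).  The caller is invariant to global
  multiplicative scaling of either sample, and targets with zero normal
  coverage are masked.

## Phylogenies and clustering concordance

Per patient, binary mutation profiles (SNV/indel keys plus non-neutral
CNV states, equally weighted) give a Manhattan distance matrix; pairs with
missing entries are rescaled by total/observed keys.  Trees are built with
BioNJ: standard neighbor-joining selection via the Q criterion, NJ
two-point branch lengths, and a reduction weight $\lambda \in [0, 1]$ that
minimises the variance of the reduced distances under $\mathrm{Var}(d)
\propto d$.  Ties on Q are broken by the lexicographically smallest pair
of subtree labels, so results are deterministic; negative branch-length
estimates are clamped to zero with the deficit moved to the sibling edge.
On additive matrices the reconstruction is exact (topology and lengths to
$10^{-9}$; asserted against random generating trees).  A driver labels a
branch when its carrier set matches one side of the branch's bipartition;
drivers carried by all tumor samples are truncal, and carrier sets
matching no bipartition are reported as homoplasy/inconsistent.

Cohort-level dendrograms use complete linkage: Euclidean distance on the
1,000 largest-variance normalized methylation loci, Manhattan distance for
mutation profiles.  The mutation metric/linkage for the cross-cohort
dendrogram is not dictated by the methylation choice; Manhattan + complete
is adopted for consistency with the per-patient trees and can be
overridden.  Per-patient concordance on a dendrogram is scored as:
*complete* when some node's leaf set equals the patient's tumor samples
exactly; *partial* when some node's leaf set is a proper subset (≥ 2) of
them; *none* otherwise.  The partial rule is a formalisation chosen here —
published reports give verdict counts, not a rule.  Single-sample patients
are trivially complete and flagged.

## The synthetic cohort generator

`cohort_design()` fixes the study conditions; the generators are
deterministic given the seed (fixed per-stage seed offsets, so stages can
be rerun in isolation).

* **Methylation counts** are negative binomial with mean
  $\mu_{gi} = R_i \, b_g \, 2^{u_{gp} + t_i \cdot \mathrm{logFC}_g}$:
  per-sample library sizes (nephrectomies uniform on 5×10⁵–10⁶ fragments,
  biopsies scaled to 25–50% of that), a per-core baseline $b_g$ (normalized
  gamma draws), a per-patient per-core Gaussian offset $u_{gp}$ (SD 0.5 on
  the log2 scale by default — strong enough that patient identity
  dominates the top-variance loci, as observed in real multi-region
  methylome data), and an injected treatment log-fold-change on designated
  target cores.  Dispersion 0.05 is a typical capture-seq value.  2,000
  cores with 48 two-core target genes keep every run fast while leaving a
  realistic background for the variance trend.
* **Variants** draw Poisson numbers of truncal/shared/private somatic and
  germline variants per patient with the corresponding carrier sets, plus
  GQ, allele depths, VAF, consequence/SIFT/PolyPhen annotations and a
  21-bp reference flank kept free of homopolymer runs — except for the
  configurable fraction of calls built to violate each filter (low GQ, low
  VAF, a run placed within 1 bp of the affected span).
* **BAF tracks** are binomial allele counts at shared het-SNP positions;
  tumor success probabilities shift by `baf_shift` inside injected LOH
  segments, and shifts that would push the mean outside (0, 1) are
  rejected — segment BAF therefore never collapses to 0 or 1, the
  signature of sub-clonality/purity.
* **Coverage** per panel gene is gamma-noised around a per-gene capture
  bias, times $2^{\mathrm{logratio}}$ for genes with injected CNVs.
* A **hypoxia preset** (`hypoxia_design()`) gives 2 patients with
  pre-/post-ligation samples and no injected effect, the sampling control.

What the generator does *not* emulate: raw reads, fragmentation or capture
chemistry, realistic genome annotation, linkage between methylation and
mutations, or the per-core coverage distribution of any particular public
dataset.  Tests passing on these cohorts therefore establish algorithmic
correctness and statistical calibration under the stated model — not
concordance with any specific deposited dataset.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive in memory; BED output is 0-based
  half-open at the file boundary.
* Quantile definition everywhere: type 7 (linear interpolation); boundary
  values go to the higher category.
* Lowess span 0.5; below 50 loci the weight trend is unreliable and unit
  weights are used with a warning.
* Degenerate tests: identical constant groups give p = 1; zero variance
  with unequal means is a flagged error, not a silent p-value.  All-zero
  paired CNV differences give p = 1.
* t-test conventions: pooled-variance (Student) for the unpaired
  comparisons, as is conventional for these small cohort comparisons.

## Problem sizes used in the checks

The shipped test-suite and acceptance checks use the defaults above
(2,000 cores, 14 patients, 56 tumor samples) for end-to-end statistical
checks, 100 random 5–10-taxon trees for BioNJ exactness, 1,000 random
p-vectors for the BH oracle, 50 seeds per shift for LOH boundary
recovery, and 20 cohorts for the concordance property — sizes chosen so
each property is measured with useful Monte-Carlo resolution while the
whole suite stays quick on a laptop.

## Known limitations

* The moderated-t p-values on negative-binomial counts are slightly
  anticonservative in the far tail (a property shared by the reference
  voom/eBayes implementation they are checked against); at the FDR < 0.1
  threshold over 48 target genes this means a false companion discovery
  accompanies a true one in roughly a fifth of simulated cohorts.
* Absolute FDR values for a given dataset depend on the blocked/grouped
  design choice and on the restriction family (cores vs genes); both are
  exposed as options, and per-gene summaries take the smallest-p core per
  gene.
* The CNV and LOH callers are deliberately simple; they are not drop-in
  replacements for purpose-built exome CNV tools and do not estimate
  purity or ploidy.
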