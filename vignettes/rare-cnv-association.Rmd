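---
title: "Rare germline CNV calling and gene-centric association: methods"
author: "rareCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare germline CNV calling and gene-centric association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Rare germline copy-number variants (CNVs) — deletions and duplications of
genomic segments — can disrupt gene dosage and are enriched for deleterious
effects relative to single-nucleotide variants of the same frequency. In a
case–control cohort genotyped on a SNP array, CNVs leave two footprints in
the per-probe intensity data: the Log R Ratio (LRR) shifts down under a
deletion and up under a duplication, and the B-allele frequency (BAF) loses
its heterozygous band under a deletion. Because individual rare CNVs are too
infrequent to test directly, evidence is aggregated per gene: any CNV
overlapping a gene makes its sample a *carrier*, and carrier status is
tested against disease status.

`rareCNV` implements the whole chain — quality control, calling, annotation,
global burden analysis, three gene-centric association models with Bayesian
false discovery probabilities, and downstream characterisation — together
with a synthetic cohort generator with known embedded truth, so that every
stage is testable without access-controlled genotype data.

# Intensity quality control

## Derivative log ratio spread (DLRS)

Per-probe noise is summarised per sample as the SD of successive
within-chromosome LRR differences divided by $\sqrt 2$:

$$\mathrm{DLRS} = \frac{\mathrm{sd}\,(x_{i+1}-x_i)}{\sqrt 2}.$$

Differences are never taken across a chromosome boundary. The $\sqrt 2$
divisor makes DLRS an unbiased estimator of the per-probe noise SD for
independent noise, and differencing makes it insensitive to slowly varying
trends, so it isolates probe-to-probe noise from genomic waves. This is the
standard array-QC formalisation of "spread of neighbouring-probe
differences"; the verbal definition admits alternatives (e.g. mean local
variance), which is why the formula is fixed here explicitly.

Samples are excluded when their DLRS exceeds the cohort mean by more than
3.5 cohort SDs, once before and once after principal-component adjustment
(the second threshold is recomputed among samples surviving the first
pass). Exclusion is single-pass per stage, not iterated to convergence:
with tens of thousands of samples a second iteration changes the mean and
SD negligibly, and single-pass semantics make the filter idempotent and
order-stable.

## Principal-component adjustment

Genomic waves (long-range smooth distortions of LRR) and batch intensity
artifacts are shared across samples with sample-specific loadings. After
mean-centring each probe, the top $k$ sample-space principal components of
the probes-by-samples matrix are removed (economy SVD via the
samples-by-samples cross-product). The default is $k = 10$, configurable;
the residual matrix is exactly orthogonal to the removed components, and a
pure rank-$k$ artifact is removed exactly.

Two practical cautions, both visible in the synthetic experiments: with
very small cohorts (tens of samples) the leading components can absorb part
of a long CNV carried by a single sample, attenuating its signal; and PCA
can only absorb artifacts that are *shared* across samples. Both effects
shrink rapidly with cohort size and are negligible at the hundreds-of-
samples scale used in the tests.

## Heterozygosity and other sample filters

BAF heterozygosity is the fraction of probes with BAF strictly inside
(0.2, 0.8). Samples more than 4.89 SD from the cohort mean (either
direction) are excluded, as are samples flagged with sex-chromosome
abnormalities (consumed as a flag; karyotype inference is out of scope).
The 4.89-SD "excess heterogeneity" rule follows the array-QC convention
from large consortium pipelines; the underlying statistic is not uniquely
pinned down by that phrase, and BAF heterozygosity is the interpretation
adopted here.

## Probe filters

Probes are removed when the array clustering (GenTrain-like) score is below
0.15, mean intensity is below 0.2, or the LRR variance exceeds the mean
probe variance by more than 2 SD. All boundaries are strict as printed: a
probe exactly at a cut point is kept.

# CNV calling

Adjusted LRR is standardised per probe across samples (mean 0, SD 1,
$n-1$ denominator), expressing each sample's intensity in units of that
probe's cohort noise — the natural scale for *rare* events, since fewer
than 3% of samples can shift any probe's distribution.

Each sample's z-track is then segmented per chromosome by penalised
least-squares mean-shift change-point detection, implemented as an exact
dynamic program (optimal partitioning) with a bounded maximum segment
length of 256 probes. The bound is what makes the program $O(nW)$ rather
than $O(n^2)$: pruned exact solvers (PELT) only achieve linear time when
change-points are dense, and rare-CNV data is the opposite regime. Because
calls are capped at 200 probes, any callable event fits inside the bound
and its recovery is exact; the only consequence is that long change-free
stretches are represented as chains of near-zero-mean segments, which can
never cross a call threshold. The penalty is $3\log n$ per chromosome of
$n$ probes.

Segments become calls when they span 3–200 probes and their mean z crosses
$-2.5$ (deletion) or $+2.0$ (duplication). The asymmetry mirrors array
physics: a one-copy loss shifts LRR by about $-0.5$ while a one-copy gain
shifts it by about $+0.3$, so duplications sit closer to the noise. These
defaults are calibrated only against the recovery property below.

Calls are then filtered: any call overlapping ($\geq$ 1 bp) an exclusion
region (immune loci, centromere/telomere stand-ins) is dropped; samples
left with $\geq$ 50 calls are excluded outright (excess CNV count indicates
poor-quality DNA or clonal artifacts); calls are grouped into loci by
$\geq$ 50% reciprocal overlap and equal type (transitively closed), and
loci carried by more than 3% of samples are dropped — the method is
designed for rare variation, and common CNVs are better served by
genotype-cluster approaches. The reciprocal-overlap grouping rule is a
design choice; published analyses rarely state theirs.

Recovery, measured on synthetic cohorts (500 samples, 20,000 probes,
events of $\geq$ 10 probes with |shift|/noise $\geq$ 3), exceeds 90% at
$\geq$ 50% reciprocal overlap, with fewer than 0.5 false calls per sample
on an event-free genome (observed: $\approx$ 98% and $\approx$ 0.01).
Sensitivity for 3–5-probe duplications is intrinsically poor at these
thresholds, consistent with the high published false-discovery rates for
few-probe duplications on arrays.

# Annotation and burden

Coordinates are 1-based inclusive throughout; BED I/O converts at the
boundary. Overlap of $\geq$ 1 bp with a gene body makes a call genic, with
an exon exonic; strand is ignored (dosage is strand-agnostic). When a gene
has several transcripts the longest defines its boundary. Genes outside
chromosomes 1–23/X are rejected at load. For every (call, gene) pair the
containment relation is recorded, because the loss-of-function model needs
to know whether a duplication spans the whole gene.

Global burden compares mean per-sample call counts between cases and
controls for each genomic class (all, genic, exonic, intergenic) crossed
with type (all, deletions, duplications): a pooled-variance (Student)
two-sample t-test, a 95% CI on the mean difference from the pooled SE with
$n_1+n_2-2$ df, and fold change defined as the ratio of group means. The
pooled (rather than Welch) form follows the stated test; the CI
construction on the mean difference is the natural reading of the reported
intervals.

# Gene-centric association

Three carrier models per gene:

* **DEL** — any deletion overlapping the gene;
* **DUP** — any duplication overlapping the gene;
* **LOF** — every deletion, plus duplications that *partially* overlap the
  gene. A duplication containing the entire gene leaves an intact copy and
  is excluded; a duplication breaking inside the gene — including one fully
  internal to the gene body — disrupts the transcript and is included. The
  fully-internal case is not settled by the phrase "partially overlapped";
  counting it as disruptive is the biologically motivated reading adopted
  here.

A sample counts once per gene per model, and LOF carriers are a superset of
DEL carriers by construction. Each gene with at least one carrier is tested
by logistic regression of status on the carrier indicator with no
covariates; with a single binary predictor the MLE equals the crude 2x2
odds ratio, so the closed form (Wald SE $\sqrt{\sum 1/\text{cell}}$) is
used whenever all four cells are nonzero, and separation falls back to
Firth penalised likelihood (damped Newton on the modified score), which is
finite for any table and reduces, for this saturated design, to adding 1/2
to each cell. Genes with zero carriers are not tested, which is why each
model has its own Bonferroni denominator: the threshold is
$0.05/n_\text{genes tested}$ per model. Associations with $p<0.01$ are
candidates.

## Bayesian false discovery probability

For a log odds-ratio estimate $\hat\theta$ with variance $V$, the Bayes
factor of the null against a $N(0, W)$ alternative is

$$\mathrm{BF} = \sqrt{\frac{V+W}{V}}\;
  \exp\!\left(-\frac{Z^2}{2}\frac{W}{V+W}\right),
  \qquad Z = \hat\theta/\sqrt V,$$

and the false discovery probability is
$\mathrm{BF}\cdot\mathrm{PO}/(\mathrm{BF}\cdot\mathrm{PO}+1)$ with prior
odds of the null $\mathrm{PO} = (1-\pi_1)/\pi_1$. Prior probabilities of
association are tiered: 0.5 for established high-penetrance genes, 0.2 for
genes with prior evidence, 0.05 otherwise (the default for genes absent
from the prior table). The prior SD is set from an upper odds-ratio bound
of 8.0 interpreted as the 97.5th percentile of the prior:
$W = (\ln 8 / 1.96)^2$. The percentile convention is the standard one for
this approximation; the bound itself reflects the rare, large-effect
regime of the tested CNVs.

# Downstream characterisation

Candidate CNVs are intersected with risk-SNP tables: a *direct* overlap
puts the lead SNP inside the CNV; an *LD proxy* overlap requires a proxy
with $r^2 > 0.8$ (strict) inside. Over-representation of candidate genes in
user-supplied gene sets uses the one-sided hypergeometric tail with
Bonferroni correction across sets — the same core test behind the usual
web-based enrichment services, applied to local gene sets only. Expression
is categorised from TPM with lower-inclusive bins (< 0.5 not detected,
0.5–10 low, $\geq$ 10 high; the source notation uses open intervals that
leave the boundary values unassigned). Dosage sensitivity requires a
positive Spearman rank correlation between copy number and expression with
two-sided $p < 10^{-4}$; rank correlation is chosen because expression
responses to dosage need not be linear, and the choice of correlation is
not otherwise determined.

# The synthetic cohort generator

The generator is a first-class, tested module defining the study
conditions:

* probe grid: regular spacing (default 5 kb) on a configurable number of
  chromosomes; per-probe clustering-score and intensity metadata with small
  low-quality tails, so the probe filters engage;
* noise: per-sample Gaussian LRR noise with SD drawn from
  $N(0.10, 0.02^2)$ (truncated), matching the post-adjustment DLRS scale of
  production arrays;
* waves: 3 smooth sinusoidal genome-position components with per-sample
  Gaussian loadings (amplitude 0.05), exactly absorbable by PCA — which
  makes the adjustment step testable against an exact oracle;
* events: background count per genome Poisson with mean 4.9 (controls)
  times a burden multiplier 1.22 (cases); 56.6% deletions; 3–20 probes per
  event; LRR shifts $-0.5$ (DEL) and $+0.3$ (DUP); loci exceeding a 3%
  carrier ceiling are resampled or thinned;
* risk genes: designated genes receive events at configured case/control
  carrier frequencies (the mechanism behind the power checks);
* BAF: heterozygous band near 0.5 in diploid regions, lost under
  deletions, split towards 1/3 and 2/3 under duplications.

The rate, multiplier, deletion fraction and noise scale are the published
cohort-level figures of large CNV association studies of this design; the
intensity shifts are the standard one-copy magnitudes for Illumina-style
arrays (no intensity model is published for the study design itself, so
the asymmetric $-0.5/+0.3$ convention is adopted and configurable).

What the generator does **not** emulate: GC-correlated wave structure
(waves here are generic smooth components), allele-specific cluster
geometry, X-chromosome dosage, mosaic (sub-clonal) events, and
linkage-disequilibrium structure beyond a user-supplied proxy table.
Passing tests therefore demonstrate the statistical machinery and the
calling engine under a faithful noise/burden model, not performance on
real array idiosyncrasies.

One scale effect deserves emphasis: per-probe standardisation estimates
the noise from the cohort itself, so on a *small, dense* synthetic genome
the carriers inflate the per-probe SD and attenuate z-shifts. The recovery
and association checks therefore use genomes sparse enough (event
occupancy well below 1% of probe-samples) to sit in the regime the method
is designed for; real 500k-probe arrays are far sparser still.

# Problem sizes and replicate counts

The test suite runs, by choice, at the largest sizes that keep the full
suite comfortably interactive: caller recovery on 500 samples x 20,000
probes (about 2,500 events) plus a 200-sample null genome; burden-test
calibration on 5,000 replicate null cohorts of 200+200 samples; gene-test
calibration on about 20,000 null genes at the study's arm sizes (4,115
cases, 17,818 controls) with carrier frequencies 0.5–2%; burden-multiplier
recovery on 2,000+2,000 genomes; risk-gene power on 100 replicates at
4,000/18,000 with carrier frequencies 0.5% vs 0.05%. The calibration
replicate counts are set from the binomial SE so that the Monte Carlo
error is several times smaller than the acceptance bands (5% $\pm$ 1% and
1% $\pm$ 0.3%); at only a few hundred replicates those bands would be
indistinguishable from Monte Carlo noise.

# Numerical choices and degenerate inputs

* DLRS requires $\geq$ 3 probes and $\geq$ 2 within-chromosome differences.
* Standardisation refuses zero-variance probes (they must be filtered).
* The Firth fallback uses damped Newton with step-halving on the penalised
  likelihood (plain Newton oscillates for singleton carriers).
* `burdenTest` refuses groups of fewer than 2 samples and zero pooled
  variance with unequal means; an all-zero class in the burden table is
  reported with means and a flagged undefined p-value.
* A constant copy-number vector makes dosage sensitivity untestable and is
  flagged, not guessed.
* Ties in segmentation are resolved by the earliest change-point
  (deterministic backtracking); all generators run from explicit seeds and
  identical configurations are byte-identical.

# Known limitations

* No covariate adjustment (study site, ancestry PCs) in the association
  models; the design tested none.
* Integer copy-number genotyping (CN = 0 vs 1), BAF-informed calling and
  mosaicism are out of scope.
* Few-probe duplications are called with low sensitivity at the default
  thresholds — a property of the data, not a tuning artifact.
* The LD expansion consumes a precomputed proxy table; no LD is computed
  from reference panels.

# Reproducing the headline numbers

```{r, eval = FALSE}
library(rareCNV)
cfg <- simulationConfig(seed = 1)
res <- runPipeline(cfg, "pipeline_out")
res$summary$mean_cnvs_per_sample
res$summary$burden
res$summary$n_candidate_genes
```

`scripts/acceptance.R` recomputes all of the quantities discussed here from
scratch on seeded synthetic cohorts and writes them as JSON.
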