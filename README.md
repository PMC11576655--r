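# rareCNV

Rare germline copy-number variant (CNV) calling and gene-centric
case–control association analysis from SNP-array intensity data.

Rare CNVs — deletions and duplications carried by fewer than 3% of a
cohort — alter gene dosage and are strongly enriched for deleterious
effects, but individual events are too infrequent to test directly.
`rareCNV` is for statistical geneticists running array-based case–control
studies: it takes per-probe Log R Ratio (LRR) and B-allele frequency (BAF)
matrices through quality control, calling, annotation, global burden
analysis and three gene-centric genome-wide association models, and ships a
synthetic cohort generator with known embedded truth so the entire pipeline
is testable end to end without access-controlled genotype data.

## What it computes

* **Sample QC** — derivative log ratio spread
  `DLRS = sd(x[i+1] − x[i]) / √2` per sample (within chromosomes only),
  with exclusion above mean + 3.5 SD before and after adjustment; BAF
  heterozygosity outliers (4.89 SD); sex-abnormality flags.
* **Wave/batch adjustment** — removal of the top *k* (default 10)
  sample-space principal components of the probe-centred LRR matrix.
* **Calling** — per-probe z-scores across samples; exact penalised
  least-squares mean-shift segmentation per sample and chromosome (bounded
  segment length, O(nW)); calls at mean z ≤ −2.5 (DEL) or ≥ +2.0 (DUP)
  spanning 3–200 probes; exclusion-region, ≥50-calls-per-sample and
  3%-carrier-frequency rarity filters with 50% reciprocal-overlap locus
  grouping.
* **Annotation & burden** — ≥ 1 bp gene/exon overlap (longest transcript
  defines the gene boundary); per-sample counts by
  {all, genic, exonic, intergenic} × {ALL, DEL, DUP}; pooled-variance
  Student t-tests with CIs on the mean difference and fold change =
  ratio of group means.
* **CNV-GWAS** — per-gene carrier sets under deletion-only,
  duplication-only and loss-of-function models (LOF = all deletions plus
  gene-disrupting duplications); logistic regression equal to the 2×2 odds
  ratio, with Firth penalised likelihood under separation; per-model
  Bonferroni thresholds `0.05 / n_genes_tested`; candidates at p < 0.01;
  Wakefield Bayesian false discovery probability
  `BF = √((V+W)/V)·exp(−Z²W/(2(V+W)))` with tiered priors
  π₁ ∈ {0.5, 0.2, 0.05} and prior SD from an odds-ratio bound of 8
  (`W = (ln 8 / 1.96)²`).
* **Downstream** — risk-SNP colocalisation (direct or LD proxy with
  r² > 0.8), hypergeometric over-representation with Bonferroni
  correction, TPM expression categories, and Spearman dosage sensitivity
  (positive, p < 1e−4).

## Worked example

```r
library(rareCNV)
cfg <- simulationConfig(seed = 1, nCases = 200, nControls = 400,
  riskGenes = data.frame(gene = "GENE010",
                         case_freq = 0.02, control_freq = 0.002))
res <- runPipeline(cfg, "pipeline_out")
```

This simulates a 600-sample cohort (background 4.9 CNVs per control
genome, 1.22-fold case excess, one planted deletion risk gene), runs every
stage, and prints from `res$summary`:

```
mean CNVs per sample: 4.09
              stage n_samples
              input       600
        qc_excluded         0
 cnv_count_excluded         0
           analysis       600
      class mean_cases mean_controls fold_change  p_value
        all      4.645          3.82        1.22 1.82e-06
      genic      0.840          0.63        1.33 2.52e-03
     exonic      0.805          0.62        1.30 6.78e-03
 intergenic      3.805          3.19        1.19 1.17e-04
genes tested: DEL DUP LOF
 40  40  40
Bonferroni thresholds:     DEL     DUP     LOF
0.00125 0.00125 0.00125
candidates (p<0.01): DEL DUP LOF
  1   0   1
```

The burden rows read exactly like a published global-burden table: cases
average 4.65 rare CNVs against 3.82 in controls (fold change 1.22 — the
embedded excess, recovered), the excess is stronger for genic than
intergenic events here, and the per-model Bonferroni cut is 0.05/40 genes
tested. `res$results$assoc$LOF` holds the per-gene table (carriers, OR,
CI, p, BFDP); on this small cohort the planted gene ranks near the top but
background events overlapping genes by chance keep single-gene power
modest — at published cohort sizes (thousands of cases, 500k probes) the
same machinery resolves it cleanly.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/cnvpipe.R run --config pipeline.yaml --out-dir out/
Rscript inst/cli/cnvpipe.R simulate --out-dir sim/ --seed 7
```

## Package layout

S4 core: `CNVIntensitySet` (a `RangedSummarizedExperiment` with `lrr`/`baf`
assays and probe metadata), `SimulationConfig`, `AnnotatedCNVs`; accessors
`lrr()`, `baf()`, `probeRanges()`, `sampleStatus()`, `cnvCalls()`,
`geneHits()`. The methods vignette
(`vignettes/rare-cnv-association.Rmd`) documents the model, the tunable
parameters and their defaults, what the generator does and does not
emulate, and the numerical choices.
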