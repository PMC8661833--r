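---
title: "Post-Mendelian severity modelling with the Integrated PolyGenic Score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-Mendelian severity modelling with the Integrated PolyGenic Score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipgs)
library(dplyr)
```

## The model

COVID-19 severity after SARS-CoV-2 infection is driven by age, sex, and a
polygenic host-genetic component spanning the whole allele-frequency
spectrum: a single ultra-rare loss-of-function variant can behave almost
Mendelianly, while common coding polymorphisms nudge risk weakly. `ipgs`
implements a post-Mendelian modelling framework that combines both ends of
the spectrum in a single interpretable per-patient score, the Integrated
PolyGenic Score:

$$
\mathrm{IPGS} \;=\; (n^s_C - n^m_C) \;+\; F_{LF}\,(n^s_{LF} - n^m_{LF})
\;+\; F_R\,(n^s_R - n^m_R) \;+\; F_{UR}\,(n^s_{UR} - n^m_{UR}),
$$

where $n^s$ and $n^m$ count, per patient, the active gene-level Boolean
features associated with severity and mildness in each frequency class
(common $\geq 5\%$, low-frequency 1–5%, rare 0.1–1%, ultra-rare $<0.1\%$,
reference-population MAF), and the weights $F$ model the greater penetrance
of rarer variants, with $F_C$ anchored at 1.

The pipeline has five stages, each an exported function:

1. **Boolean encoding** (`encode_cohort()`): protein-impacting variants are
   collapsed per gene into 12 sample-by-feature 0/1 matrices — frequency
   class × inheritance model. Collapsed classes use the dominant
   ($\geq 1$ variant), recessive ($\geq 2$ variant alleles), and X-linked
   ($\geq 1$ variant in an X gene) rules; common variants instead get one
   feature per combination of a gene's variants plus an "absence" feature,
   a haplotype-like encoding.
2. **Phenotype adjustment** (`adjust_phenotypes()`): per sex, a
   proportional-odds model of the 6-grade outcome on age defines each
   patient's *expected* grade; patients matching expectation are excluded
   and the rest are labelled more/less severe than expected. Selection
   therefore sees only the signal that age and sex cannot explain.
3. **Feature selection** (`bootstrap_select()`, `null_threshold()`,
   `finalize_features()`): per bootstrap iteration (100 × 90% subsamples by
   default) an L1-penalised logistic model is fitted per representation,
   with the regularisation strength chosen by 10-fold cross-validation over
   50 log-spaced strengths in $[10^{-2}, 10^{1}]$ under a 0.5-SD parsimony
   rule. A feature's selection count is compared against a threshold from
   an identical run with permuted labels; only features strictly above the
   null threshold enter the score.
4. **Weights** (`optimize_weights()`): exhaustive integer grid search
   ($F_{LF} \in [1,4]$, $F_R \in [2,8]$, $F_{UR} \in [5,100]$) maximising
   the silhouette coefficient of the 1-D scores under the two
   adjusted-phenotype classes; per-bootstrap optima are aggregated by their
   median.
5. **Severity model** (`fit_severity_model()` and friends): weighted
   logistic regression of the binary severity label (hospitalised with any
   respiratory support) on percentile-normalised IPGS, age in decades, and
   sex, with inverse-class-frequency weights; evaluated by
   confusion-matrix metrics, a shuffled-IPGS permutation null, Welch
   t-tests of the score distributions, and odds-ratio analyses.

`rank_genes()` finally converts the selection ledger into a weighted gene
ranking, $W_g = \sum |\bar\beta| \times \text{count} \times F$, with fixed
multipliers (ultra-rare 5, rare 4, low-frequency 2, common 1), emitted as a
GSEA-preranked `.rnk` file. Enrichment analysis itself is out of scope.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(simulation_config(n_samples = 1200, seed = 1))
fit <- run_pipeline(sim$variants, sim$phenotypes,
                    config = ipgs_defaults(cv_folds = 5L),
                    n_boot = 25, seed = 2)
glance(fit)
```

On this cohort the pipeline retains a few percent of the Boolean features,
estimates weights with the ultra-rare class dominating (the shipped
default weights are `F_LF = 2, F_R = 4, F_UR = 5`), and the
IPGS + age + sex model beats the age + sex baseline on held-out samples
with a shuffled-IPGS permutation p-value below 0.05 (the README shows one
captured run).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `maf_breaks` | 0.001 / 0.01 / 0.05 | class boundaries (fraction), left-closed |
| `n_boot` | 100 | bootstrap iterations (selection and null run) |
| `subsample_frac` | 0.9 | per-iteration subsample, drawn without replacement |
| `cv_folds`, `lambda_grid` | 10, 50 points in $[10^{-2}, 10^1]$ | LASSO strength search |
| `sd_rule` | 0.5 | parsimony band (SDs of the best point's fold scores) |
| `null_percentile` | 95 | upper-tail percentile of the null selection counts |
| `grid_f_lf/r/ur` | 1–4 / 2–8 / 5–100 | integer weight grids |
| `combination_cap` | 6 | per-gene variant cap for full subset enumeration |

Boundary closure deserves a note: the frequency classes are implemented
left-closed (e.g. rare is $0.001 \le \mathrm{MAF} < 0.01$), with a
`boundary = "results"` switch for the right-closed reading, because the two
conventions appear in circulation and only boundary-exact MAFs differ.

The null threshold is the **upper-tail** 95th percentile of the null
selection-count distribution. A literal lower-tail 5th percentile of a
distribution that is mostly zeros would be 0 and would exclude nothing;
excluding false positives "with 95% confidence" requires the upper tail.
The lower-tail behaviour remains available via `null_percentile = 5`.

## Numerical choices

* **Expected grade** is the cutpoint interval of the linear predictor,
  $\zeta_{k-1} < \eta \le \zeta_k$ — the easily interpretable threshold
  reading of the proportional-odds fit (and its modal category for a
  single predictor). Absent grade levels collapse their cutpoints with a
  warning; a constant-age stratum yields slope 0 with a warning. Age
  enters in raw years by default (`age_scale = "decades"` is available).
* **CV score** is classification accuracy; the chosen strength is the
  *largest* one within half an SD of the best mean accuracy, trading a
  sliver of score for sparsity. Folds are stratified by class so every
  training fold sees both labels.
* **Ties at the null threshold are dropped** (strict `>`), the
  conservative reading of a 95%-confidence exclusion.
* **Silhouette** is computed exactly for 1-D scores and two fixed clusters
  in $O(n \log n)$ via sorted prefix sums (`silhouette_binary()`); the
  test suite cross-checks it against the naive $O(n^2)$ definition and
  `cluster::silhouette()`. Grid ties break toward the lexicographically
  smallest $(F_{UR}, F_R, F_{LF})$. A degenerate grid (all scores
  constant) returns the grid minima with a warning.
* **AR allele counting** treats a homozygous call as two alleles and two
  heterozygous calls in one gene as compound-heterozygous by proxy: exome
  data are unphased, so cis/trans cannot be distinguished. A hemizygous
  male X call satisfies "homozygous" in common-variant AR combinations.
* **Combination explosion**: all $2^k - 1$ subsets are enumerated for
  genes with at most `combination_cap` common variants; beyond the cap
  only genotype patterns actually observed in the cohort are used (with a
  warning), since full enumeration is exponential. All-zero feature
  columns are pruned at cohort level — they could never be selected —
  except absence features, which are structural.
* **Percentile normalisation** uses mid-ranks, so ties share a percentile
  and a singleton cohort maps to 0.5.
* **Decision threshold** for the severity model is 0.5 on the predicted
  probability, paired with inverse-class-frequency weights during
  fitting; perfect separation is flagged and resolved by a lightly
  ridge-penalised refit. Permutation p-values are one-sided upper-tail
  with add-one correction; t-tests are Welch by default.
* **Multi-allelic sites** are treated as independent variants per alt
  allele (`chrom:pos:ref:alt` keys). Y, MT and X pseudo-autosomal
  variants (GRCh38 windows by default) are excluded: only autosomal and
  X-linked inheritance models are defined.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes, not real exomes. Severity is generated on a proportional-odds
latent scale — age slope $-0.04$/year, male effect $-0.8$, logistic noise,
five cutpoints giving a realistic grade spread for a SARS-CoV-2-positive
cohort (ages $\mathcal N(55, 17)$ truncated to [18, 95], balanced sexes) —
and planted gene effects enter the same latent scale, so phenotype
adjustment, selection, weight optimisation and the final model are all
exercised by one generator. Defaults plant one severity and one mildness
feature in each of the four frequency classes with log-odds 1.1 (odds
ratio about 3, the effect size at which recovery is expected to be
reliable) at class-plausible carrier rates (0.05–0.3).

What it does **not** model: linkage disequilibrium, population structure,
a realistic site-frequency spectrum (reference MAFs are uniform within
each class interval, and cohort carrier rates are set independently of the
reference MAF, as in a disease cohort enriched for carriers), sequencing
error, or annotation noise. Passing tests therefore demonstrate that the
procedures are implemented correctly and behave as designed under their
own assumptions — not that the headline numbers of any real cohort are
reproduced. Published cohort-level figures (e.g. accuracies near 0.73 or
specific odds ratios) depend on multi-cohort consortium data far beyond
desk scale and are deliberately not asserted anywhere in this package.

## Problem sizes used by the shipped checks

The validation suite scales the protocol down to a single CPU while
keeping its structure: bootstrap depth 25 instead of 100 (and 5-fold CV in
the heaviest simulations), cohorts of 400–2000 samples with 10–200
background genes, 20 replicates for calibration/ordering properties, 50
for the model-improvement property, and parameter-recovery checks at
n = 5000. The acceptance script runs the full pipeline on a 1200-sample
default-condition cohort at bootstrap depth 25. These sizes are design
choices recorded here so results are reproducible at the same scale.

## Known limitations

* Selection operates per representation; interactions between frequency
  classes are only combined downstream, in the score.
* The silhouette objective is one-dimensional by construction; weight
  identifiability degrades when a class carries no signal (ties then
  resolve to the grid minima, which is intended but means "no evidence",
  not "evidence for the minimum").
* The severity model takes the percentile-normalised score, so absolute
  calibration across cohorts relies on within-cohort normalisation, as in
  the original design.
* VCF ingestion trusts upstream annotation for gene assignment and
  protein impact; no re-annotation or liftover is attempted.
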