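# ipgs — Integrated PolyGenic Score modelling of COVID-19 severity

`ipgs` is an R implementation of a post-Mendelian framework for predicting
COVID-19 severity from exome variants. It is written for statistical
geneticists who want an interpretable gene-level alternative to classical
polygenic risk scores: instead of summing genome-wide SNP effects, it
collapses protein-impacting coding variants into per-gene Boolean features
stratified by allele-frequency class and inheritance model, selects the
features associated with an age/sex-adjusted severity phenotype, and
combines them into one score per patient:

```
IPGS = (nC_s − nC_m) + F_LF·(nLF_s − nLF_m) + F_R·(nR_s − nR_m) + F_UR·(nUR_s − nUR_m)
```

where `n*_s` / `n*_m` count the patient's active severity / mildness
features among common (MAF ≥ 5%), low-frequency (1–5%), rare (0.1–1%) and
ultra-rare (< 0.1%) variants, and the weights `F` — found by a silhouette
grid search, `F_C` fixed at 1 — model the greater penetrance of rarer
variants. The score then enters a weighted logistic model together with
age and sex to predict severe outcome (hospitalisation with any
respiratory support, grade ≤ 4 on a 6-level outcome scale).

The pipeline stages (each an exported, pipe-friendly function taking a
data frame and returning a tibble):

| stage | functions |
|---|---|
| I/O & validation | `read_variant_table()`, `read_vcf()`, `read_phenotypes()`, writers |
| Boolean encoding | `classify_frequency()`, `encode_cohort()` (12 representations) |
| Phenotype adjustment | `fit_ordinal_age_model()`, `adjust_phenotypes()` |
| Feature selection | `lasso_fit_one()`, `bootstrap_select()`, `null_threshold()`, `finalize_features()` |
| Score | `count_components()`, `compute_ipgs()`, `optimize_weights()`, `ipgs_scores()` |
| Severity model | `fit_severity_model()`, `evaluate_severity_model()`, `permutation_significance()`, `score_distribution_test()`, `odds_ratio_analysis()` |
| Gene ranking | `rank_genes()`, `write_rnk()` |
| Simulation & orchestration | `simulation_config()`, `simulate_cohort()`, `make_toy_fixture()`, `run_pipeline()` |

Fitted objects support `tidy()`, `glance()`, `autoplot()` and
`plot_score_distribution()`. A thin command-line wrapper lives at
`inst/cli/ipgs.R` (`simulate`, `encode`, `adjust`, `select`, `fit-ipgs`,
`run-all`).

## Worked example

```r
library(ipgs)

sim <- simulate_cohort(simulation_config(n_samples = 1200, seed = 1))
fit <- run_pipeline(sim$variants, sim$phenotypes,
                    config = ipgs_defaults(cv_folds = 5L),
                    n_boot = 25, seed = 2)
glance(fit)
```

One run of exactly this (the acceptance script below, seed 1) printed:

```
accuracy  (IPGS + age + sex) : 0.694
accuracy  (age + sex only)   : 0.583
permutation p (accuracy)     : 0.005
t-test p (IPGS by severity)  : 2.8e-35
optimised weights (F_LF, F_R, F_UR): 2, 2, 5
features surviving the null threshold: 2.6% of 613
planted genes recovered      : 8 of 8
```

Read: on a held-out partition of a synthetic cohort with planted genetic
effects, adding the IPGS lifts accuracy eleven points over the age + sex
baseline; shuffling the IPGS column destroys the gain (empirical p ≈
0.005); the score distributions of severe and mild patients separate
decisively; the bootstrap-LASSO + permutation-null selection keeps a few
percent of the candidate features and finds every planted gene.

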