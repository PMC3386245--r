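# decohort

Case/control transcriptomic cohort analysis with the genetics that follows
from a transcription-factor finding.

Post-mortem brain expression studies compare a few dozen disease and
control samples on a microarray, adjust for tissue-quality covariates
(RIN, post-mortem interval, age at death), and then chase the hits: is the
significant gene list enriched for targets of one transcription factor?
Do disease-associated SNPs regulate those targets differently in cases
than in controls? Do the targets mediate the factor's association with
disease? Do other cohorts agree? `decohort` implements that full chain as
a set of tidy, pipeable R functions, for analysts who work with
probe-level expression tables, PLINK-style genotype exports and GWAS
summary statistics.

## What it computes

* **Preprocessing** — probe removal by detectable-range (per-group > 50%)
  and quality-flag (> 75% of arrays) rules, median collapse of replicated
  probes, quantile normalization, log2 (`filter_probes()`,
  `collapse_replicates()`, `quantile_normalize()`), plus the five-step
  control-gene normalization for bead-panel validation experiments
  (`quantigene_normalize()`).
* **Differential expression** — per-probe OLS
  `y ~ status + RIN + PMI + age`, two-sided t test on the status
  coefficient, Benjamini–Hochberg FDR, fold change `2^|beta|`
  (`run_diffexpr()`, `fit_probe()`, `bh_fdr()`, `fold_change()`).
* **Enrichment** — fold enrichment and uncorrected Pearson chi-square with
  odds ratios for TFBS gene sets, the direction-of-change test (do in-set
  significant probes go up in cases more often?), and top-gene overlap
  between studies (`set_enrichment()`, `direction_enrichment()`,
  `overlap_test()`, `chi2_2x2()`).
* **eSNP scan** — the 2-df model `y ~ g + status + g:status + covariates`
  vs `y ~ status + covariates` (F test) with dominant-coded genotypes,
  stratified case/control slopes, and the eigenvalue-based effective
  number of tests with Bonferroni/Šidák thresholds (`run_esnp()`,
  `fit_2df()`, `effective_tests()`, `corrected_threshold()`).
* **Mediation** — the three-regression decomposition of a hub gene's
  effect on disease through each candidate mediator, with betas
  standardized to a shared latent logistic scale (`sqrt(var(lp) + pi^2/3)`)
  and a Sobel Z test; reports direct and indirect effects, their ratio and
  % of total effect mediated (`mediation_fit()`, `run_mediation()`,
  `sobel_z()`, `standardize_beta()`).
* **Meta-analysis** — sample-size-weighted Z combination of p-values with
  direction strings (`+`, `-`, `?`), and fixed-effect inverse-variance
  combination with genomic-control SE inflation and the Rsq < 0.30
  imputation filter (`weighted_z_meta()`, `inverse_variance_meta()`,
  `genomic_lambda()`, `rsq_filter()`, `run_meta()`).
* **Synthetic cohorts** — a seeded generator producing expression, flags,
  covariates, gene sets, LD genotypes and summary statistics with known
  truth (differential expression enriched in a TFBS set, one injected
  eSNP, a hub→mediator→liability model), so every stage runs and can be
  scored with no external data (`simulate_cohort()`, `sim_config()`,
  `simulate_ld_genotypes()`, `simulate_mediation_cohort()`).
* **Pipeline** — `run_pipeline()` executes the stages on files and writes
  per-stage TSVs plus a reproducibility manifest; `run_demo()` simulates a
  cohort and runs everything end to end from one seed.

## Worked example

Simulate a 27-case / 26-control cohort, preprocess, and walk the stages:

```r
library(decohort)
library(dplyr)

sim  <- simulate_cohort(sim_config(seed = 3))
filt <- filter_probes(sim$expr, sim$flags, sim$samples)
norm <- quantile_normalize(collapse_replicates(filt$expr))
de   <- run_diffexpr(norm, sim$samples, annotation = sim$annotation)
glance(de)
#> # A tibble: 1 × 4
#>   n_probes n_fdr_significant n_fc_gt_1.5 frac_up_in_case
#>      <int>             <int>       <int>           <dbl>
#> 1     9713               120           5           0.493
```

Of 9,713 probes surviving QC, 120 pass FDR < 0.05. Is the hub
transcription factor's binding-site set over-represented among them?

```r
sig <- filter(de, q < 0.05)
set_enrichment(unique(na.omit(sig$gene)), unique(na.omit(de$gene)), sim$sets)
#>   set_name    k_sig_in_set n_sig fold_enrichment odds_ratio        p bonferroni_p
#> 1 TFBS_hub              61   120           1.590      2.229 8.07e-06     4.84e-05
#> 2 TFBS_decoy1            6   120           0.502      0.472 6.79e-02     4.07e-01
#> ...
```

The injected set (generative odds ratio 2) is recovered at OR 2.23 and
survives Bonferroni; the decoys do not. The injected eSNP — genotype
effect −0.49 with an extra −0.24 in cases — is recovered by the 2-df
model, with the case-stratum slope steeper than the control slope:

```r
es  <- sim$truth$esnp
m   <- as.matrix(as.data.frame(norm[, -1])); rownames(m) <- norm$probe_id
fit <- fit_2df(m[es$probe_id, ], dominant_code(sim$geno$dosage[[es$snp_id]]),
               sim$samples, snp_id = es$snp_id, probe_id = es$probe_id)
glance(fit)
#>   snp_id  probe_id statistic         p_2df    p_lrt n_used
#> 1 rs00001 P001605       28.4 0.00000000934 5.60e-10     53
tidy(fit)
#>   term                estimate std.error      p.value
#> 1 genotype              -0.625    NA     NA
#> 2 genotype:status       -0.191    NA     NA
#> 3 genotype (cases)      -0.942     0.139  0.000000808
#> 4 genotype (controls)   -0.617     0.143  0.000313
```

Mediation of the hub's effect through its targets, one mediator at a
time (direct/indirect effects standardized to one latent scale; Sobel
p ≤ 0.05 retained):

```r
med <- run_mediation(norm, sim$samples, sim$truth$hub_probe,
                     sim$truth$mediators$probe_id)
summarize_mediation(med)
#>   mediator_id direct_effect indirect_effect ratio_indirect_direct pct_total_mediated     p
#> 1     P000551          0.35            0.22                  0.62               0.38 0.039
```

`autoplot()` methods draw the volcano plot (`de`), the
expression-by-genotype boxplots (`fit`) and the enrichment dot plot;
`run_demo(out_dir, seed = 3)` writes all of the above, stage by stage,
from files to files with a manifest.

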