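# traitmod

Linking a behavioral trait to brain gene co-expression modules,
neuropathology, cognitive decline and Alzheimer's dementia.

`traitmod` is an R package for analysts working with community-based aging
cohorts that combine ante-mortem phenotyping (e.g. NEO Five-Factor
personality scores, annual cognitive testing) with postmortem molecular data
(bulk cortical RNA-seq summarized into co-expression modules, regional
β-amyloid and phosphorylated-tau burdens, a pathological AD diagnosis). It
implements the full inference chain from trait to dementia as tested,
reusable components, and ships a synthetic-cohort generator with planted
effects so the whole pipeline is verifiable without access to controlled
data.

## What it computes

* **Covariate-adjusted association scans.** Every scan is OLS
  `y ~ x + covariates` with two-sided *t* inference, complete-case per model:
  trait–module scans, gene-level scans with Benjamini–Hochberg FDR over
  exactly the scanned gene family, additive-dosage SNP scans (monomorphic
  SNPs flagged, never dropped), region-specific pathology scans, and the
  trait–decline model refit under a ladder of covariate sets to expose
  attenuation by pathology adjustment.
* **Permutation omnibus test.** The trait is shuffled across subjects and
  the full module scan rerun B times; the observed count of modules with
  nominal P < α is located in the permutation distribution with the add-one
  estimator *p* = (1 + #{b : S_b ≥ S_obs}) / (B + 1). Empirical QQ
  confidence envelopes (90/95%) come from the order statistics of the same
  null.
* **Causal mediation (ACME/ADE).** Quasi-Bayesian Monte Carlo on the linear
  structural equations `M ~ T + X`, `Y ~ T + M + X`: ACME = a·b,
  ADE = c′, total = a·b + c′ per coefficient draw, percentile intervals and
  add-one MC P values; chain mediation over
  trait → module → TAU → decline → AD (logistic outcome model for the binary
  terminus); a direction-consistency check; and an instrumental-variable
  pleiotropy screen (instrument candidate vs pleiotropic vs uninformative).
* **Over-representation analysis.** One-sided hypergeometric tests of a hit
  list against GMT gene sets with BH adjustment, universe defaulting to the
  QC-surviving genes.
* **Preprocessing.** The prevalence-style low-count gene filter (keep a gene
  iff ≥ 100 subjects have ≥ 4 reads, both thresholds configurable),
  z-score-mean (or eigengene) module summaries, square-root pathology
  transforms with a global burden per mark, and per-subject OLS
  cognitive-decline slopes.

## Worked example

```r
library(traitmod)

study <- simulate_study(cohort_config(n_subjects = 466, seed = 7),
                        rosmap_like_effects(), n_genes = 2000, n_modules = 47)

scan <- trait_module_scan(study$data, study$module_expr, "neuroticism")
head(scan[order(scan$p), c("outcome", "beta", "se", "p", "n_used")], 4)
#>  outcome        beta          se            p n_used
#>       m6  0.01806287 0.004054784 1.061286e-05    466
#>      m13 -0.01443864 0.003878088 2.217265e-04    466
#>       m7  0.01316260 0.003670794 3.728865e-04    466
#>      m20  0.01233655 0.004167885 3.239826e-03    466
sum(scan$p < 0.05)
#> [1] 12

null <- build_permutation_null(study$data, study$module_expr, "neuroticism",
                               B = 1000, seed = 8)
omnibus_p(scan, null)
#> Permutation omnibus test (count statistic, B = 1000)
#>   observed statistic: 12
#>   empirical P: 0.000999001

fit_mediation(study$data, "neuroticism", "m7", "cog_slope",
              covariates = default_covariates("base"), n_sims = 2000, seed = 9)
#> Causal mediation (neuroticism -> m7 -> cog_slope, gaussian outcome)
#>   ACME : -0.000484 [-0.0008619, -0.0001889]  P = 0.0009995
#>   ADE  : 0.0002769 [-0.0008752, 0.001438]  P = 0.6667
#>   Total: -0.0002071 [-0.001363, 0.0009494]  P = 0.7356
#>   Proportion mediated: 2.34   (n = 466, sims = 2000)
```

Reading the output: 12 of 47 module summaries associate with the simulated
trait at nominal P < 0.05 — far more than the ~2.4 expected under the null —
and none of the 1000 trait relabelings reaches that count, so the omnibus
P is at the estimator floor 1/1001 ≈ 0.001: the trait has a broad,
collectively non-random transcriptomic footprint. The mediation fit
decomposes the (here weak) trait–decline association into the path through
module m7 (ACME) and the residual direct path (ADE); with the planted chain
the mediated path carries essentially all of the signal.

The same stages run as one orchestrated pipeline with per-stage TSV/JSON
outputs and a checksummed manifest:

```r
man <- run_pipeline(demo_config(out = "run1", seed = 7))
```

## Package layout

* `R/cohort.R` — synthetic cohort, expression, genotype and downstream
  generators (`simulate_study()`).
* `R/preprocess.R` — gene filter, module summaries, pathology transform,
  decline slopes.
* `R/association.R` — the OLS engine and all scans; BH adjustment.
* `R/omnibus.R` — permutation null, omnibus P, QQ envelopes.
* `R/mediation.R` — quasi-Bayesian mediation, chain mediation, direction
  test, IV screen.
* `R/enrichment.R` — GMT reading and hypergeometric over-representation.
* `R/pipeline.R` — `run_pipeline()` orchestration with manifest.
* `vignettes/trait-module-pipeline.Rmd` — the methods account: models,
  assumptions, parameter choices, generator scope and limitations.
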