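---
title: "From a personality trait to dementia: module association, permutation omnibus testing and causal mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a personality trait to dementia: module association, permutation omnibus testing and causal mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitmod)
```

# The analysis problem

Community-based aging cohorts with prospective autopsy make it possible to ask
how a behavioral exposure — here a personality trait such as neuroticism,
scored with the NEO Five-Factor Inventory — relates to the molecular state of
the cortex and, through it, to Alzheimer's dementia. The data structure is a
subject-level spine (trait scores, demographic and technical covariates)
joined against four molecular/clinical layers: bulk cortical RNA-seq
summarized into co-expression modules, immunohistochemical β-amyloid and
phosphorylated-tau (TAU) burdens in eight brain regions, a per-subject slope
of cognitive decline estimated from annual testing, and a pathological AD
diagnosis.

`traitmod` implements the full inference chain on that structure:

1. covariate-adjusted linear association scans at the module, gene and SNP
   level,
2. a permutation omnibus test asking whether the *set* of module P values is
   collectively incompatible with the null, with empirical QQ envelopes,
3. Benjamini–Hochberg FDR control over gene-level scans,
4. region-specific pathology associations,
5. an instrumental-variable pleiotropy screen, and
6. a quasi-Bayesian linear causal-mediation engine, including chain mediation
   over trait → module → TAU → decline → AD.

Because the motivating cohort data are controlled-access, the package ships a
synthetic-cohort generator that reproduces the data structure with known
planted effects, so that every stage is testable end to end.

# Models and procedures

## Association scans

All continuous outcomes are modeled by ordinary least squares with an
intercept,

$$ y_i = \alpha + \beta\, x_i + \mathbf{z}_i^\top \boldsymbol\gamma + \varepsilon_i, $$

and inference on $\beta$ uses the two-sided $t$ test with the residual
degrees of freedom. `fit_linear_association()` is the single engine behind
every scan; it works on complete cases per model (recording `n_used`),
one-hot encodes categorical covariates with the first level as reference,
and codes sex as female = 1. Two standard covariate sets are predefined:
`base` (age at death, sex, education, race, study) and `base_rna` (base plus
postmortem interval, RNA-seq batch and RIN), the latter used for all
expression outcomes.

Degenerate designs are handled explicitly rather than by crashing mid-scan: a
constant predictor or outcome yields a flagged row with `p = NA`; a
numerically perfect fit reports the floor P value (`.Machine$double.xmin`)
so it is never confused with an untestable association; covariates that are
constant on the analysis sample (e.g. race in a nearly homogeneous
subsample) are dropped from that model; any remaining rank deficiency is an
error naming the collinear columns. Monomorphic SNPs are flagged, never
silently dropped.

## Module summaries

Modules are an *input* (a gene → module map from any clustering method); the
package only summarizes them. The default summary of a module is the mean
across member genes of per-gene z-scores (each gene standardized across
subjects). This is the simplest statistic consistent with "the expression
level of the module", is invariant to gene order, and reduces to the gene's
own z-score for singleton modules. A first-principal-component
("eigengene") summary is available via `method = "eigengene"`; its sign is
aligned with the mean z-score so the two summaries correlate positively.
Genes with zero variance contribute nothing (their z-score is set to 0), and
modules with no retained genes are dropped with a warning.

## The permutation omnibus test

A single module association is rarely decisive; the interesting question is
whether the full vector of $M$ module P values deviates from uniformity. The
empirical null is built by shuffling the trait across subjects — covariates
and expression stay attached to their subjects — and rerunning the complete
covariate-adjusted scan $B$ times (`build_permutation_null()`). The default
omnibus statistic is the count of modules with nominal $P$ below
$\alpha = 0.05$; the observed statistic is located in the permutation
distribution with the add-one estimator

$$ p_{\text{omnibus}} = \frac{1 + \#\{b : S_b \ge S_{\text{obs}}\}}{B + 1}, $$

which can never return 0 and, under exchangeability, is valid
($\Pr(p \le \alpha) \le \alpha$ on the achievable grid). Ties count as
exceedances — the conservative choice. The count statistic was chosen
because an excess of nominally significant modules is the natural
description of a broad, diffuse transcriptomic signal; a `"sumlog"`
statistic ($\sum_m -\log_{10} p_m$) is provided as a sensitivity analysis
and agrees directionally on strongly signaled data. The observed data are
never included in the null matrix.

QQ confidence envelopes come from the same null: for rank $r$, the envelope
at level $\ell$ spans the empirical $(1\pm\ell)/2$ quantiles of the $r$-th
order statistic of $-\log_{10} p$ across permutations, against the expected
line $-\log_{10}(r/(M+1))$. The bands are pointwise per rank (a simultaneous
band would be wider); this matches how such envelopes are normally drawn and
read. Under the null the $r$-th order statistic of $M$ uniform P values is
Beta$(r, M-r+1)$, which the test suite uses as a closed-form check on the
envelope medians.

## FDR families

`bh_adjust()` applies Benjamini–Hochberg step-up adjustment (via
`stats::p.adjust`, verified in the tests against the literal
$\min_{j \ge i} p_{(j)} m / j$ definition). The FDR family in
`gene_scan_with_fdr()` is exactly the set of genes scanned in one call —
e.g. all genes of the trait-associated modules jointly — never the whole
transcriptome implicitly. Whether to adjust jointly or per module is the
caller's choice of gene set; joint is the default reading.

## Causal mediation

For a triple (treatment $T$, mediator $M$, outcome $Y$) the engine fits the
two linear structural equations

$$ M = \alpha_1 + a\,T + \mathbf{z}^\top\boldsymbol\gamma_1 + \varepsilon_1,
\qquad
Y = \alpha_2 + c'\,T + b\,M + \mathbf{z}^\top\boldsymbol\gamma_2 + \varepsilon_2, $$

and propagates estimation uncertainty by quasi-Bayesian Monte Carlo: draw
coefficient vectors from their asymptotic normal distributions, form per
draw the mediated effect $\mathrm{ACME} = a b$, the direct effect
$\mathrm{ADE} = c'$ and the total effect $ab + c'$. Point estimates are draw
means, intervals are 2.5/97.5 percentiles, and P values are two-sided Monte
Carlo tail probabilities with an add-one correction. With no
treatment–mediator interaction, the identity
$\widehat{ab} + \widehat{c'} = \hat\tau$ (the coefficient of $T$ in
$Y \sim T + \mathbf{z}$) holds exactly for the point fits and within Monte
Carlo error for the draws; the tests assert it on every fitted dataset. No
interaction term is modeled by default because a single ACME/ADE pair is the
reported quantity of interest.

A binary terminal outcome (the AD diagnosis) is handled with a logistic
outcome model; the mediation effects are then reported on the latent
log-odds scale. This convention is stated here explicitly because mixing
linear mediator models with a logistic outcome model admits several scales;
the latent scale keeps the product-of-coefficients logic intact.

`chain_mediation()` walks an ordered chain (e.g. trait, module, TAU, decline
slope, AD) and fits one triple per consecutive window — three fits for a
five-variable chain. `direction_test()` fits a triple in both orientations
and reports which carries the stronger mediated signal; it is labeled a
heuristic consistency check on cross-sectional data, not a causal proof. A
reverse mediator model that is essentially deterministic
($R^2 > 1 - 10^{-6}$) is flagged degenerate instead of producing meaningless
draws.

## Instrumental-variable screen

A SNP can anchor a Mendelian-randomization argument for trait → module only
if it affects the module exclusively through the trait. The decision rule in
`iv_verdict()` formalizes the screen: with threshold $\alpha$,

* `instrument_candidate`: SNP–trait $P < \alpha$ and trait-adjusted
  SNP–module $P \ge \alpha$;
* `pleiotropic`: SNP–trait $P < \alpha$ and trait-adjusted SNP–module
  $P < \alpha$ (the SNP reaches the module around the trait);
* `uninformative`: otherwise.

`iv_pleiotropy_check()` computes the three covariate-adjusted regressions
and applies the rule. Full MR estimators are deliberately out of scope: the
screen exists precisely to decide whether MR is admissible.

## Over-representation analysis

`enrich()` performs the classical one-sided hypergeometric (Fisher) test per
gene set with BH adjustment across the sets tested in the call. The
background universe defaults to the genes surviving the expression filter —
the set actually at risk of being scanned — rather than the whole genome.
Gene sets are read from standard GMT files.

# The synthetic cohort generator

`simulate_study()` emulates the motivating cohort's structure from one
master seed (per-stage substreams are derived deterministically, so every
layer is byte-reproducible):

* **Demographics** (`cohort_config()` defaults): 466 subjects, 62% female,
  age at death 88 (6.8) years, education 16.7 (3.5) years, 99% white, two
  parent studies, postmortem interval 7 (4) hours, 8 RNA-seq batches, RIN
  7 (1). Trait scores are rounded, clipped Gaussians with the published
  means/SDs on the 0–48 NEO composite scale (a 0–36 presentation is a
  config switch; 48 is the default since it is the instrument's native
  12-item × 0–4 scoring).
* **Expression**: a latent-factor model. Each module has a per-subject
  standard-normal factor, shifted by any planted standardized trait or SNP
  effect; member genes are `loading × factor + noise` with loadings uniform
  on [0.4, 0.9]. This reproduces the one property downstream analysis uses —
  genes within a module co-vary, modules are mutually independent — without
  pretending to model transcription. An optional negative-binomial counts
  layer (log link on the latent level) feeds the low-count QC filter; all
  statistics consume the latent matrix, mirroring analysis of post-QC
  normalized data.
* **Genotypes**: Hardy–Weinberg Binomial(2, MAF) dosages, no LD. Planted
  per-allele trait effects are added to the *unclipped* latent trait draw
  and the visible score re-derived, so genetic effects act before score
  clipping.
* **Pathology**: square-root-scale global burdens (TAU 2.0 (1.3), amyloid
  1.5 (1.1), matching the published summary scale) driven by module
  summaries and SNP effects; the eight regional values scatter around the
  global burden and are squared back to the raw scale, so the preprocessing
  transform recovers them.
* **Cognition and AD**: at least two annual visits per subject
  (2 + Poisson(4)); the latent slope is
  `slope_mean + tau_to_slope × sqrt(mean regional TAU) + noise` (so a
  noiseless chain is exactly identifiable from the transformed global TAU);
  AD is a Bernoulli draw from a logistic model on the standardized
  *estimated* slope, anchored at 40% prevalence.

The demonstration effect specification (`rosmap_like_effects()`) encodes the
chain with the physically expected signs — a broad field of weak trait
effects across a dozen modules plus stronger effects on four, one module
raising TAU, TAU steepening (lowering) the slope, and a steeper slope
raising AD odds. Its magnitudes are calibrated once to the motivating
study's qualitative findings at n = 466: module-level trait associations in
the nominal 10^-2 range, a clearly detectable TAU → decline link (the
well-established strong arm of the chain), and a mediated trait → decline
path that is detectable while the direct path is not. Recovery tests instead plant an all-positive-sign chain so
that every triple's mediated effect is positive; the generator is agnostic
about sign and the tests say what they check.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: linkage disequilibrium between SNPs,
realistic count overdispersion structure and library-size variation, batch
effects on expression (batch is simulated as a covariate only), nonlinear or
interactive effects, informative missingness, and measurement error in the
trait itself. Mediation conclusions on real data additionally rest on
sequential ignorability, which no simulation can validate.

# Numerical conventions and problem sizes

* The low-count filter keeps a gene iff at least `min_subjects` (default
  100) subjects have at least `min_reads` (default 4) reads. The motivating
  QC rule is phrased ambiguously ("less than 4 reads in 100 individuals");
  this prevalence-style reading is the standard one, and both thresholds are
  arguments.
* Global pathology is `sqrt(mean(raw regional values))` — transform last,
  following the stated order of operations; `mean_of_sqrt` is a switch.
* The omnibus estimator floor is $1/(B+1)$; with the conventional $B = 1000$
  the smallest reportable omnibus P is ≈ 0.001.
* Quantiles in the QQ envelope use the default type-7 definition; envelope
  levels are 0.90 and 0.95 unless overridden.
* Mediation defaults: `n_sims = 1000` draws (at least 100 enforced), seeded;
  the default covariate set for mediation is the `base` set, since pathology
  variables may themselves be on the causal path.
* Test and check problem sizes, chosen to exercise the methods at realistic
  scale while keeping a full run to a couple of minutes: null-calibration
  cohorts use n = 466, 47 modules × 10 genes, B = 199 over 200 replicates;
  the envelope closed-form check uses B = 2000; mediation coverage uses 100
  replicates at n = 500 with 1000 draws; the end-to-end chain recovery uses
  40 replicates at n = 500. The demonstration pipeline simulates 2000 genes
  in 47 modules.

# Known limitations

* Because all trait → pathology flow in the synthetic chain passes through a
  single module with moderate effects, the *marginal* trait–TAU association
  in simulated data is much weaker than the mediated path itself; real
  cohorts have many parallel paths. The demonstration output reflects this.
* Per-subject slopes are plain OLS, not mixed-model BLUPs; with very few
  visits they are noisy, which attenuates downstream associations.
* The direction test compares mediated signal strength between orientations;
  it cannot adjudicate causality and is reported with that caveat attached.
* The pipeline's plot-ready tables (QQ envelope, volcano, region-by-mark
  target table) are TSVs; no figures are rendered, keeping headless runs
  dependency-free.

# A worked pipeline run

```{r, eval = FALSE}
library(traitmod)
man <- run_pipeline(demo_config(out = "run1", seed = 7))
man$omnibus_p          # permutation omnibus P for the demo cohort
list.files("run1")     # eight stages of TSV/JSON outputs plus manifest.json
```

The manifest records the seed, thresholds, statistic choice and an MD5
checksum per output; rerunning with the same configuration and seed
reproduces every file byte-identically.
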