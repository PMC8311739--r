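---
title: "Methods: immune-related lncRNA pair signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-related lncRNA pair signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irlncPairs)
```

## The model

`irlncPairs` builds prognostic signatures from *pairs* of immune-related
long noncoding RNAs (irlncRNAs). The elementary feature is the
relative-expression-ordering indicator of a gene pair (A, B) inside one
sample:

$$ S_i(s) = \mathbf{1}\{\,x_A(s) > x_B(s)\,\}, $$

i.e. 1 when A is expressed above B within sample *s* and 0 otherwise
(ties score 0). Because the comparison happens entirely within a sample,
$S_i$ is invariant to any strictly increasing per-sample transform of
expression — library size, FPKM vs TPM units, log transforms — which is
the property that makes pair signatures portable across platforms
without normalization. This is the same idea as top-scoring-pair (k-TSP)
classifiers, transplanted into a Cox proportional-hazards setting.

The patient-level risk score is a linear functional of the indicators,

$$ \mathrm{RiskScore}(s) = \sum_{i=1}^{k} \beta_i\, S_i(s), $$

with coefficients from a multivariate Cox model over the selected pairs.
Patients are dichotomized at the cut-point $c^*$ whose two-group Cox
model minimizes the Akaike information criterion; scores above $c^*$ are
the high-risk group.

## Pipeline stages and their parameters

1. **Immune-coexpression screen** (`screen_irlncrnas`). A lncRNA (by
   annotation biotype) is immune-related when its Pearson correlation
   with any immune-list gene on the $\log_2(x+1)$ scale exceeds 0.6 with
   p < 0.001 (t-transform of r with n − 2 df, raw p by design — the
   screen is a filter, not an inference). The default screens |r| with a
   `mode = "positive"` alternative, and uses all samples
   (`samples = "tumor"` available); both conventions are echoed in the
   run report because published protocols rarely state them.
2. **Differential expression** (`de_screen`). logFC is the difference of
   mean $\log_2(x+1)$ between tumor and normal; a gene passes at
   |logFC| > 1 and BH-FDR < 0.05 (both strict). The default test is the
   Wilcoxon rank-sum test — assumption-light and adequate for the
   moderate effect sizes the screen demands; `method = "limma"` switches
   to the limma moderated t-statistic for users who want the classical
   microarray-style engine. The pipeline downstream is agnostic to the
   DE engine.
3. **Pair construction** (`build_pairs`, `prevalence_filter`). All
   C(m, 2) pairs of the DEirlncRNAs, canonically oriented by gene-symbol
   order (coefficient signs absorb orientation, so results are
   orientation-invariant). A pair is *valid* when each indicator value
   covers at least 20% of samples (boundaries inclusive): an indicator
   that is almost constant carries no prognostic contrast and
   destabilizes the penalized fits.
4. **Univariate screen** (`univariate_screen`). Single-covariate Cox per
   pair, Wald p < 0.01. (Published descriptions of this protocol mix
   p < 0.01 and p < 0.05 between sections; the threshold is a config key
   `screen_p` and the run report prints the value used.)
5. **Repeated cross-validated Lasso-Cox** (`repeated_lasso`). Each
   repetition redraws its own 10-fold partition from a per-repetition
   RNG stream spawned from one master seed, picks the
   deviance-minimizing lambda (`rule = "1se"` available) and credits the
   pairs with nonzero coefficients. Pairs selected in strictly more than
   `freq_threshold` repetitions survive. The reference protocol is 1000
   repetitions with threshold 100 (`preset = "paper"`); the `fast`
   preset scales both by ten (100/10), preserving the 10:1 ratio, and is
   what the tests and the acceptance script use.
6. **Stepwise multivariate Cox** (`stepwise_multivariate`).
   Bidirectional AIC-stepwise from the full model over the surviving
   pairs; if the full fit does not converge the selection falls back to
   forward-only and the model is flagged. The fitted coefficients are
   the signature's $\beta_i$.
7. **Cut-point and evaluation** (`aic_cutpoint`, `evaluate_auc`).
   Cut-point candidates are midpoints between consecutive unique scores
   inside the 10th–90th percentile band with at least 10 subjects per
   side — published group sizes for this signature class (roughly 90 vs
   310 of 400) sit far from the extremes, and the guard prevents
   degenerate groups. Ties go to the smaller cut-point; an infeasible
   candidate set falls back to the median, flagged. "Maximum inflection
   point" language in published descriptions is operationalized as the
   AIC-minimizing dichotomization — the only AIC-based reading — with a
   Youden-index cut on the time-dependent ROC behind
   `method = "youden"` for sensitivity analysis. Time-dependent AUCs at
   1, 3 and 5 years use the cumulative/dynamic IPCW estimator (cases:
   event by t; controls: under observation beyond t; weights from the
   Kaplan-Meier estimate of the censoring distribution). Clinical
   comparator AUCs use numeric-coded covariates as scores.
8. **Validation and associations** (`survival_comparison`,
   `chisq_association`, `score_by_stratum`, `independence_cox`,
   `group_feature_tests`, `spearman_risk_correlation`). Chi-square is
   Pearson without continuity correction (`yates` flag available);
   between-group score and feature comparisons use the Mann-Whitney
   rank-sum test — protocols in this literature often say "Wilcoxon
   signed-rank", but no pairing exists between independent risk groups,
   so the rank-sum test is the statistic actually computable. Immune
   deconvolution estimates and drug IC50 values are *inputs*: the
   package consumes the aggregate tables (TIMER2.0-style long layout or
   a plain wide matrix) and never reimplements the deconvolution
   methods. Rather than silently dropping cell types that disagree
   between methods, every (cell type, method) row is reported and a
   `consensus` flag marks cell types whose significant directions agree
   across at least two methods. Raw p at 0.05 is the flagging rule, with
   a BH-adjusted column alongside.

## Cox machinery

`cox_fit` wraps the Efron-tie-corrected partial-likelihood maximizer of
the `survival` package (the de facto reference implementation) and
reports Wald p-values and confidence intervals, matching forest-plot
convention. Constant covariates are dropped with a warning and reported
with $\beta = 0$, HR = 1; monotone-likelihood fits (separation) are
flagged and their coefficients capped at ±15 so downstream consumers
never see runaway estimates. Penalized paths and cross-validated lambda
selection delegate to `glmnet` (covariates standardized internally,
coefficients reported on the original 0/1 scale); at $\lambda = 0$ the
path reproduces the unpenalized fit to ~1e-7 and at
$\lambda \ge \lambda_{\max}$ it is exactly zero, and the test suite
holds both ends against independent oracles (a grid-search maximizer of
the explicit partial likelihood, and a hand-evaluated Efron sum). The
time-dependent ROC is implemented in this package because no installed
dependency provides the IPCW cumulative/dynamic estimator; with no
censoring it reduces to the classical Mann-Whitney AUC, which is how it
is tested.

## What the synthetic data emulate

`simulate_cohort` generates cohorts with planted, recoverable ground
truth at the scale of a TCGA bladder-cancer style study: 400 tumors and
19 normals by default.

* **Coexpression**: each of 120 planted irlncRNAs shares a standard
  normal latent factor with one immune gene (loading ρ = 0.75, safely
  above the 0.6 screen).
* **Differential expression**: 100 of those lncRNAs (and their immune
  partners — immune genes are themselves differentially expressed in
  tumors, and sharing the shift keeps the planted correlation at or
  above ρ) get a tumor-mean log2 shift of magnitude
  `de_log2fc * (1 + Exp(2))` with `de_log2fc = 1.5`, above the logFC > 1
  screen; `de_log2fc = 0` yields an exactly null shift for calibration
  runs. Signs are 80% up, echoing the up/down imbalance typical of
  tumor DE sets.
* **Planted pairs**: 10 pairs among the DE lncRNAs; members of a pair
  share their baseline mean, tumor shift and immune partner, so the
  indicator is an i.i.d. Bernoulli(1/2) column — the cleanest possible
  recovery target. True coefficients have |β| uniform in [0.5, 1] with
  random signs.
* **Survival**: per tumor sample, $\eta = \sum \beta_i S_i$; event times
  are Weibull proportional hazards (exponential by default,
  `weibull_shape` exposed for robustness checks) with baseline hazard
  0.08/year. That baseline keeps the solved censoring window long
  enough that the 1-, 3- and 5-year ROC horizons all retain cases and
  controls across the β draws the config produces (checked over 20
  draws during design). Censoring is administrative-uniform on (0, τ)
  with τ solved numerically for the 35% target — the mechanism behind
  heavy administrative censoring in registry cohorts.
* **Clinical covariates**: age is Normal(68, 10) plus a 2·η coupling
  (so age is prognostic only through the planted risk — the structure
  behind the attenuation checks); stage (I–IV) and grade are
  latent-logistic ordinals shifted by η; sex is independent
  (Bernoulli(0.7) male, matching the strong male skew of bladder
  cancer).
* **Associations**: cell-type fractions are a per-sample softmax of
  `base + w·η + noise` with w > 0 for macrophage/monocyte/neutrophil/
  fibroblast/endothelial-like types and w < 0 for CD4/dendritic/
  eosinophil-like types; per-drug log-IC50 couples positively for the
  gefitinib-like drug, negatively for cisplatin/docetaxel-like drugs
  and not at all for the gemcitabine-like drug; among the checkpoint
  genes only TNFRSF9 is coupled. These are the direction patterns this
  signature class reports, and they give the association stage a known
  answer key.

Gene-level parameters are a function of the config seed while sample
noise comes from a separate stream, so `simulate_expression(cfg,
sample_seed = ...)` yields an independent validation cohort with
identical gene-level structure — that is how the held-out AUC is
computed.

**What the generator does not emulate** (and therefore what passing
tests do not show about real data): library-size and batch artifacts,
count-level noise, correlated lncRNA blocks beyond the single latent
factor, non-proportional hazards, informative censoring, and missing
clinical fields. Recovery rates on this generator are an upper bound on
what TCGA-like data would give.

## Numerical choices and degenerate inputs

* All log transforms are $\log_2(x+1)$; abundances are taken as-is
  (FPKM-like), and gene matching is by upper-cased symbol.
* Duplicate gene rows collapse by mean (order-independent); duplicate
  IDs after collapse are fatal.
* Ties in expression score 0 in the pair indicator (the literal
  "otherwise" rule); ties in risk scores resolve toward the smaller
  cut-point; score ties in the ROC count 1/2.
* Constant genes are skipped in the correlation screen (never NaN);
  constant pair indicators are skipped with a warning in the univariate
  screen; constant covariates are dropped with a warning in Cox fits.
* The prevalence boundary is inclusive with a 1e-12 guard against
  floating rounding of k/n fractions.
* Clinical time units are never converted; ROC horizons are expressed
  in years via `days_per_year = 365.25` when the clinical table is in
  days.
* The univariate screen runs through `survival::coxph.fit` directly
  (identical estimates to `coxph`, verified in the suite) because
  thousands of single-covariate fits dominate the stage's runtime.

## Design choices that were genuinely open

* **Screen order**: univariate screen → repeated Lasso → stepwise, the
  order that keeps the Lasso design matrix small; source descriptions
  are ambiguous between orderings.
* **Coexpression on all samples** rather than tumor-only (flag
  provided): the screen is about co-regulation, not tumor-specific
  signal, and normals add power at n = 419 vs 400.
* **"1000 times with 10-fold cross proof"** is read as: each repetition
  redraws its fold partition; the frequency is the count of repetitions
  in which a pair is selected at that repetition's deviance-minimizing
  lambda.
* **Cut-point horizon**: the AIC dichotomization itself needs no ROC
  horizon; `cutpoint_horizon` (default 5 years) feeds only the optional
  Youden variant. Published descriptions tie the cut-point to the
  1-year curve in one place and the 5-year curve in another; the AIC
  reading makes the conflict moot.
* **Comparator covariates** enter the ROC numerically coded (ordinal
  stage/grade integers, sex 0/1) — the simplest defensible convention
  when the source does not state one.

## Problem sizes used by the test suite

The unit suite runs on reduced cohorts (typically 150 tumors, 60
lncRNAs, 5 planted pairs) chosen so each stage still has planted signal
to find; the acceptance checks run the full default configuration
(400 tumors, 10 planted pairs) over 5 seeds with the `fast` preset, 200
seeds for the null-calibration batteries, and 20 cohorts for cut-point
recovery. Those sizes are the package's own test design; the reference
protocol (`preset = "paper"`) multiplies only the Lasso repetition count
and its frequency threshold.

## Known limitations

* The stepwise stage inherits the usual instability of stepwise
  selection; the repeated-Lasso frequency filter upstream is what keeps
  it tame, and the signature should be read as *a* minimal adequate
  model, not *the* unique one.
* No external-cohort calibration or nomogram construction is provided.
* C(m, 2) pair construction is in-memory; it is comfortable for a few
  hundred DEirlncRNAs (the intended regime) but not for thousands.
* The IPCW ROC assumes censoring independent of the score; under
  informative censoring the AUCs are biased, and the generator does not
  exercise that regime.
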