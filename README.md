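# irlncPairs

Prognostic signatures from **pairs of immune-related lncRNAs** for
survival analysis of tumor cohorts.

## The problem

Expression-level prognostic signatures travel badly between platforms:
FPKM vs TPM, batch effects and normalization choices all change the
numbers a model was trained on. Relative-expression-ordering features do
not. For a pair of genes (A, B) and a sample *s*, define

    S_i(s) = 1  if  expr(A, s) > expr(B, s),   else 0

— a within-sample comparison that is invariant to any strictly
increasing per-sample transform of expression (the k-TSP idea). This
package builds a Cox proportional-hazards risk model on such pair
indicators, restricted to immune-related, differentially expressed
lncRNAs (DEirlncRNAs), the class of regulators that shapes the tumor
immune microenvironment:

    RiskScore(s) = sum_i  beta_i * S_i(s)

with the pair set chosen by a univariate Cox screen, **repeated
cross-validated Lasso-Cox frequency selection** (1000 repetitions, each
with its own 10-fold partition; pairs selected in >100 repetitions
survive) and AIC-stepwise multivariate Cox. Patients are split into
high/low risk at the cut-point whose dichotomized Cox model minimizes
the AIC, and the groups are validated against survival (Kaplan-Meier +
log-rank), clinicopathological covariates (chi-square, rank-sum,
univariate/multivariate Cox independence), immune-infiltration estimates
and predicted drug IC50 tables (rank-sum + Spearman). Time-dependent
ROC/AUC at 1/3/5 years uses the IPCW cumulative/dynamic estimator.

It is aimed at computational biologists who have a gene-level expression
matrix (tumor + normal), a GTF annotation, an immune gene list
(ImmPort-style) and a clinical table, and want the whole pair-signature
workflow — plus a synthetic-data generator with planted ground truth so
every stage can be tested without downloading anything.

## Worked example

Simulate a study-scale cohort (400 tumors, 19 normals, 10 planted
prognostic pairs with |beta| in [0.5, 1], ~35% censoring) and run the
pipeline:

```r
library(irlncPairs)

cfg <- sim_config(seed = 1)
co  <- simulate_cohort(cfg)

res <- run_pipeline(co$expr, co$clinical, co$truth$immune_genes,
                    pipeline_config("fast", seed = 101))
print(res)
```

```
pair-signature pipeline run report
preset=fast seed=101
thresholds: r>0.6 p<0.001 (absolute, all samples); |logFC|>1 FDR<0.05 (wilcoxon);
  prevalence>=0.2; univariate p<0.01; lasso 100x10-fold, freq>10 (min);
  cutpoint horizon=5y; alpha=0.05
funnel: n_lnc_tested=300 -> n_irlncrna=120 -> n_deirlncrna=100 -> n_pairs=4950
  -> n_valid_pairs=1859 -> n_univariate=50 -> n_lasso=36 -> k_signature=21
  -> n_high=220 -> n_low=180
cutpoint=-0.26704 logrank_p=2.47e-40
auc: 1y=0.7622 3y=0.816 5y=0.8496
```

Reading the funnel: of 300 lncRNAs, 120 pass the immune-coexpression
screen (r > 0.6, p < 0.001), 100 of those are differentially expressed
(|logFC| > 1, FDR < 0.05), giving C(100,2) = 4950 pairs of which 1859
have both indicator values in at least 20% of samples; 50 survive the
univariate Cox screen, 36 the repeated-Lasso frequency filter, and the
stepwise model keeps 21 pairs. The AIC-optimal cut-point −0.267 splits
the cohort 220/180; the groups differ in survival at log-rank
p ≈ 2.5e-40, and the risk score reaches IPCW AUCs of 0.76/0.82/0.85 at
1/3/5 years. Against the planted truth, 8 of the 10 planted pairs are in
the model, all with correct coefficient signs:

```r
rec <- intersect(res$model$pairs, co$truth$pairs$pair_id)
length(rec)                                    # 8
all(sign(res$model$beta[rec]) ==
    sign(co$truth$pairs$beta[match(rec, co$truth$pairs$pair_id)]))  # TRUE
```

With real data, replace the simulated objects with the readers:

```r
expr <- read_expression("expr.tsv", "conditions.tsv")
expr <- set_gene_biotypes(expr, read_gtf_biotypes("gencode.gtf.gz"))
clin <- read_clinical("clinical.tsv", time_unit = "days")
imm  <- read_gene_list("immport_genes.txt")
res  <- run_pipeline(expr, clin, imm, pipeline_config("paper", seed = 1),
                     infiltration = read_feature_table("timer2.tsv", "infiltration"),
                     ic50 = read_feature_table("ic50.tsv", "ic50"),
                     out_dir = "results/")
```

`out_dir` receives the stage TSVs (`irlncrna.tsv`, `pairs.tsv`,
`signature.tsv`, `risk_scores.tsv`, `auc.tsv`, ROC coordinates, KM and
Cox tables, association tables) and a `run_report.txt` with every
threshold and seed echoed.

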