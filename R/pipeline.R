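# End-to-end orchestration: screen -> pairs -> select -> fit -> validate
# -> associate, with a single config object, deterministic seeding and a
# run report mirroring the stage-count funnel.

#' Pipeline configuration
#'
#' All stage thresholds in one validated object. Presets: `"paper"` runs
#' the reference protocol (1000 Lasso repetitions, frequency threshold
#' 100); `"fast"` scales both by 10 (100 repetitions, threshold 10) for
#' test-sized runs. Unknown keys are rejected.
#'
#' @param preset `"fast"` (default) or `"paper"`.
#' @param ... overrides for any of: r_threshold (0.6), p_threshold
#'   (0.001), coexpr_mode ("absolute"), coexpr_samples ("all"),
#'   lfc_threshold (1), fdr_threshold (0.05), de_method ("wilcoxon"),
#'   min_frac (0.2), screen_p (0.01), repetitions, folds (10),
#'   freq_threshold, lambda_rule ("min"), cutpoint_horizon (5),
#'   horizons (c(1,3,5)), alpha (0.05), days_per_year (365.25), seed (1).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("fast", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- list(preset = preset,
              r_threshold = 0.6, p_threshold = 0.001,
              coexpr_mode = "absolute", coexpr_samples = "all",
              lfc_threshold = 1, fdr_threshold = 0.05,
              de_method = "wilcoxon", min_frac = 0.2, screen_p = 0.01,
              repetitions = if (preset == "paper") 1000L else 100L,
              folds = 10L,
              freq_threshold = if (preset == "paper") 100L else 10L,
              lambda_rule = "min", cutpoint_horizon = 5,
              horizons = c(1, 3, 5), alpha = 0.05,
              days_per_year = 365.25, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full pair-signature pipeline
#'
#' Executes: immune-coexpression screen, tumor-vs-normal DE screen over
#' the screened lncRNAs, pair-indicator construction on the tumor samples
#' with clinical data, prevalence filter, univariate Cox screen, repeated
#' cross-validated Lasso-Cox frequency selection, stepwise multivariate
#' Cox, risk scoring, AIC cut-point dichotomization, time-dependent AUC
#' evaluation, the clinical validation battery, and (when tables are
#' supplied) the downstream association stage. Deterministic under a
#' fixed config seed. A structured run report (thresholds, seeds and the
#' stage-count funnel) is returned and, with `out_dir`, written to disk
#' alongside the stage TSV outputs.
#'
#' @param expr `ExpressionMatrix` with biotypes set.
#' @param clinical `ClinicalTable`.
#' @param immune_genes character vector of immune-related gene symbols.
#' @param config a [pipeline_config()].
#' @param infiltration,ic50,ici optional long feature tables (see
#'   [read_feature_table()]).
#' @param out_dir optional output directory for TSV artifacts and
#'   `run_report.txt`.
#' @return list of class `irlnc_pipeline` with elements `coexpr`, `de`,
#'   `pm` (filtered pair matrix), `univariate`, `lasso`, `model`,
#'   `scores`, `cut`, `assignment`, `auc`, `validation`, `assoc`,
#'   `funnel`, `report`.
#' @export
run_pipeline <- function(expr, clinical, immune_genes,
                         config = pipeline_config(),
                         infiltration = NULL, ic50 = NULL, ici = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(config, "pipeline_config"))
  funnel <- list()
  # 1. immune-coexpression screen
  coexpr <- screen_irlncrnas(expr, immune_genes,
                             r_threshold = config$r_threshold,
                             p_threshold = config$p_threshold,
                             mode = config$coexpr_mode,
                             samples = config$coexpr_samples)
  irlnc <- coexpr$lncrna[coexpr$passed]
  funnel$n_lnc_tested <- nrow(coexpr)
  funnel$n_irlncrna <- length(irlnc)
  if (!length(irlnc)) stop("screen stage: no immune-related lncRNAs found")
  # 2. DE screen over the immune-related lncRNAs
  de <- de_screen(expr, genes = irlnc, lfc_threshold = config$lfc_threshold,
                  fdr_threshold = config$fdr_threshold,
                  method = config$de_method)
  de_set <- de$gene[de$passed]
  funnel$n_deirlncrna <- length(de_set)
  if (length(de_set) < 2)
    stop("DE stage: fewer than 2 differentially expressed irlncRNAs")
  # 3. pair matrix on tumor samples with clinical data
  tum <- names(expr$sample_condition)[expr$sample_condition == "tumor"]
  tum <- intersect(tum, clinical$sample_id)
  if (length(tum) < 20) stop("pairs stage: too few tumor samples with clinical data")
  pm_all <- build_pairs(subset_expression(expr, samples = tum), de_set)
  funnel$n_pairs <- nrow(pm_all$S)
  pm <- prevalence_filter(pm_all, min_frac = config$min_frac)
  funnel$n_valid_pairs <- nrow(pm$S)
  # 4. univariate Cox screen
  uni <- univariate_screen(pm, clinical, p_threshold = config$screen_p)
  funnel$n_univariate <- uni$n_out
  # 5. repeated cross-validated Lasso-Cox
  lasso <- repeated_lasso(subset_pairs(pm, pairs = uni$kept), clinical,
                          repetitions = config$repetitions,
                          folds = config$folds,
                          freq_threshold = config$freq_threshold,
                          seed = config$seed, rule = config$lambda_rule)
  funnel$n_lasso <- lasso$n_out
  if (!length(lasso$kept))
    stop("selection stage: no pair exceeded the lasso frequency threshold")
  # 6. stepwise multivariate Cox
  model <- stepwise_multivariate(subset_pairs(pm, pairs = lasso$kept),
                                 clinical)
  funnel$k_signature <- model$k
  # 7. risk scores, cut-point, groups
  scores <- risk_score(model, pm)
  al <- align_samples(pm, clinical)
  sc <- scores[colnames(al$pm$S)]
  cut <- aic_cutpoint(sc, al$clinical$os_time, al$clinical$os_event)
  model$cutpoint <- cut$cutpoint
  assignment <- assign_risk_groups(sc, cut$cutpoint)
  funnel$n_high <- sum(assignment$group == "high")
  funnel$n_low <- sum(assignment$group == "low")
  # 8. AUC evaluation
  auc <- evaluate_auc(sc, al$clinical, horizons = config$horizons,
                      days_per_year = config$days_per_year)
  # 9. clinical validation
  validation <- list(survival = survival_comparison(assignment,
                                                    al$clinical))
  covs <- intersect(c("age", "sex", "grade", "stage"),
                    colnames(al$clinical))
  grp <- assignment$group[match(al$clinical$sample_id,
                                assignment$sample_id)]
  validation$chisq <- do.call(rbind, lapply(covs, function(v) {
    x <- al$clinical[[v]]
    if (v == "age") x <- ifelse(x >= 65, ">=65", "<65")
    chisq_association(grp, x, feature = v)
  }))
  validation$strata <- do.call(rbind, lapply(covs, function(v) {
    x <- al$clinical[[v]]
    if (v == "age") x <- ifelse(x >= 65, ">=65", "<65")
    tryCatch(score_by_stratum(sc, x, feature = v), error = function(e) NULL)
  }))
  validation$independence <- independence_cox(sc, al$clinical,
                                              covariates = covs)
  # 10. downstream associations
  assoc <- list()
  for (nm in c("infiltration", "ic50", "ici")) {
    tab <- switch(nm, infiltration = infiltration, ic50 = ic50, ici = ici)
    if (!is.null(tab))
      assoc[[nm]] <- list(
        group = group_feature_tests(tab, assignment, alpha = config$alpha),
        spearman = spearman_risk_correlation(tab, sc))
  }
  report <- c(
    "pair-signature pipeline run report",
    paste0("preset=", config$preset, " seed=", config$seed),
    paste0("thresholds: r>", config$r_threshold, " p<", config$p_threshold,
           " (", config$coexpr_mode, ", ", config$coexpr_samples,
           " samples); |logFC|>", config$lfc_threshold, " FDR<",
           config$fdr_threshold, " (", config$de_method,
           "); prevalence>=", config$min_frac, "; univariate p<",
           config$screen_p, "; lasso ", config$repetitions, "x",
           config$folds, "-fold, freq>", config$freq_threshold, " (",
           config$lambda_rule, "); cutpoint horizon=",
           config$cutpoint_horizon, "y; alpha=", config$alpha),
    paste0("funnel: ", paste(names(funnel), unlist(funnel), sep = "=",
                             collapse = " -> ")),
    paste0("cutpoint=", format(cut$cutpoint, digits = 6),
           " logrank_p=", format(validation$survival$logrank$p,
                                 digits = 4)),
    paste0("auc: ", paste(auc$auc$horizon, "y=",
                          round(auc$auc$auc, 4), sep = "",
                          collapse = " ")))
  out <- structure(list(coexpr = coexpr, de = de, pm = pm,
                        univariate = uni, lasso = lasso, model = model,
                        scores = sc, cut = cut, assignment = assignment,
                        auc = auc, validation = validation, assoc = assoc,
                        funnel = funnel, config = config, report = report),
                   class = "irlnc_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.irlnc_pipeline <- function(x, ...) {
  cat(x$report, sep = "\n")
  invisible(x)
}

#' Write pipeline artifacts to a directory
#' @param result an `irlnc_pipeline` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  stopifnot(inherits(result, "irlnc_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(result$coexpr, file.path(dir, "irlncrna.tsv"))
  write_tsv(result$de, file.path(dir, "deirlncrna.tsv"))
  write_pairs(result$pm, file.path(dir, "pairs.tsv"))
  write_tsv(result$univariate$table, file.path(dir, "selection_trace.tsv"))
  write_tsv(data.frame(pair_id = names(result$lasso$frequency),
                       frequency = unname(result$lasso$frequency)),
            file.path(dir, "lasso_frequency.tsv"))
  write_tsv(result$model$tables$multivariate,
            file.path(dir, "signature.tsv"))
  write_tsv(as.data.frame(result$assignment),
            file.path(dir, "risk_scores.tsv"))
  write_tsv(result$auc$auc, file.path(dir, "auc.tsv"))
  writeLines(format(result$cut$cutpoint, digits = 10),
             file.path(dir, "cutpoint.txt"))
  for (i in seq_along(result$auc$roc))
    write_tsv(result$auc$roc[[i]]$roc,
              file.path(dir, paste0("roc_", result$auc$auc$horizon[i],
                                    "y.tsv")))
  write_tsv(result$validation$survival$km, file.path(dir, "km.tsv"))
  lr <- result$validation$survival$logrank
  writeLines(paste0("chisq=", lr$statistic, " p=", lr$p),
             file.path(dir, "logrank.txt"))
  if (!is.null(result$validation$chisq))
    write_tsv(result$validation$chisq, file.path(dir, "clin_assoc.tsv"))
  write_tsv(result$validation$independence$univariate,
            file.path(dir, "cox_univariate.tsv"))
  write_tsv(result$validation$independence$multivariate,
            file.path(dir, "cox_multivariate.tsv"))
  for (nm in names(result$assoc)) {
    write_tsv(result$assoc[[nm]]$group,
              file.path(dir, paste0(nm, "_assoc.tsv")))
    write_tsv(result$assoc[[nm]]$spearman,
              file.path(dir, paste0(nm, "_spearman.tsv")))
  }
  writeLines(result$report, file.path(dir, "run_report.txt"))
  invisible(dir)
}
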