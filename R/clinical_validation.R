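# Validation battery for the risk groups: Kaplan-Meier survival
# difference, chi-square association with clinicopathological categories,
# rank-sum comparisons of the score across strata, and the independence
# of the risk score in univariate/multivariate Cox models.

#' Compare survival between risk groups
#'
#' Per-group Kaplan-Meier curves and the two-group log-rank test, plus a
#' per-sample table (rank by score, score, survival, group) ready for the
#' usual risk-score / survival-status scatter panels.
#'
#' @param assignment a `RiskAssignment` (see [assign_risk_groups()]).
#' @param clinical `ClinicalTable`.
#' @return list: `km` (stacked per-group curves), `logrank`, `samples`
#'   (per-sample table sorted by score), `n` per group.
#' @export
survival_comparison <- function(assignment, clinical) {
  stopifnot(inherits(assignment, "RiskAssignment"))
  m <- merge(as.data.frame(assignment), as.data.frame(clinical),
             by = "sample_id")
  if (!nrow(m)) stop("no samples shared between assignment and clinical")
  sizes <- table(m$group)
  if (any(sizes < 2))
    stop("each risk group needs >= 2 samples; sizes: ",
         paste(names(sizes), sizes, sep = "=", collapse = ", "))
  km <- do.call(rbind, lapply(levels(m$group), function(g) {
    sub <- m[m$group == g, ]
    cbind(group = g, km_estimate(sub$os_time, sub$os_event))
  }))
  lr <- logrank_test(m$os_time, m$os_event, m$group)
  samples <- m[order(m$score), c("sample_id", "score", "group", "os_time",
                                 "os_event")]
  samples$rank <- seq_len(nrow(samples))
  list(km = km, logrank = lr, samples = samples, n = as.vector(sizes))
}

#' Chi-square association between risk group and a categorical covariate
#'
#' Pearson chi-square on the 2-by-C contingency table, without continuity
#' correction by default (the strips here are large-count tables);
#' `yates = TRUE` enables the correction for 2x2 tables.
#'
#' @param group risk-group factor (2 levels).
#' @param category categorical covariate (factor or vector).
#' @param feature label for the output row.
#' @param yates apply Yates continuity correction (default FALSE).
#' @return one-row data.frame: feature, test, statistic, df, p, n.
#' @export
chisq_association <- function(group, category, feature = "category",
                              yates = FALSE) {
  tab <- table(as.factor(group), as.factor(category))
  exp_cnt <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_cnt == 0))
    stop("zero expected count in the contingency table; ",
         "merge sparse categories first")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  data.frame(feature = feature, test = "chi-square",
             statistic = unname(ct$statistic), df = unname(ct$parameter),
             p = unname(ct$p.value), n = sum(tab),
             stringsAsFactors = FALSE)
}

#' Rank-sum comparison of risk scores across clinical strata
#'
#' Pairwise two-sided Mann-Whitney (Wilcoxon rank-sum) tests between all
#' strata of a categorical covariate: exact enumeration when both groups
#' have <= 8 samples, otherwise the tie-corrected normal approximation
#' (no continuity correction). Strata with fewer than 2 samples are
#' skipped with a warning.
#'
#' @param scores numeric risk scores.
#' @param category stratum per sample.
#' @param feature label prefix for output rows.
#' @return data.frame: feature, stratum_a, stratum_b, test, statistic (U),
#'   p, effect (median difference a - b), n_a, n_b.
#' @export
score_by_stratum <- function(scores, category, feature = "category") {
  category <- factor(category)
  sizes <- table(category)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    warning("skipped strata with < 2 samples: ",
            paste(small, collapse = ", "))
  lev <- names(sizes)[sizes >= 2]
  if (length(lev) < 2) stop("need >= 2 strata with >= 2 samples")
  combos <- utils::combn(lev, 2)
  do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    a <- scores[category == combos[1, i]]
    b <- scores[category == combos[2, i]]
    exact <- length(a) <= 8 && length(b) <= 8
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = FALSE))
    data.frame(feature = feature, stratum_a = combos[1, i],
               stratum_b = combos[2, i], test = "wilcoxon rank-sum",
               statistic = unname(wt$statistic), p = wt$p.value,
               effect = stats::median(a) - stats::median(b),
               n_a = length(a), n_b = length(b),
               stringsAsFactors = FALSE)
  }))
}

#' Univariate and multivariate Cox models for risk-score independence
#'
#' Each clinical covariate (numeric-coded: ordinal stage/grade integers,
#' sex 0/1) and the risk score are fitted univariately, then jointly in
#' one multivariate Cox model. Collinear covariates are dropped with a
#' warning. Output tables are forest-plot ready (HR, CI, p).
#'
#' @param scores named per-sample risk scores.
#' @param clinical `ClinicalTable`.
#' @param covariates clinical columns to include (defaults to the ones
#'   present among age, sex, grade, stage).
#' @return list: `univariate` and `multivariate` coefficient tables.
#' @export
independence_cox <- function(scores, clinical,
                             covariates = c("age", "sex", "grade",
                                            "stage")) {
  idx <- match(clinical$sample_id, names(scores))
  ok <- !is.na(idx)
  cl <- clinical[ok, , drop = FALSE]
  covariates <- intersect(covariates, colnames(cl))
  X <- cbind(as.matrix(as.data.frame(cl)[, covariates, drop = FALSE]),
             risk_score = unname(scores[idx[ok]]))
  storage.mode(X) <- "double"
  keep_row <- stats::complete.cases(X)
  X <- X[keep_row, , drop = FALSE]
  tt <- cl$os_time[keep_row]; ev <- cl$os_event[keep_row]
  # drop exactly collinear columns (keep the first of each aliased set)
  qrX <- qr(cbind(1, scale(X, scale = FALSE)))
  if (qrX$rank < ncol(X) + 1) {
    drop_i <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)] - 1L)
    drop_i <- drop_i[drop_i >= 1]
    warning("dropped collinear covariates: ",
            paste(colnames(X)[drop_i], collapse = ", "))
    X <- X[, -drop_i, drop = FALSE]
  }
  uni <- do.call(rbind, lapply(colnames(X), function(v) {
    f <- cox_fit(tt, ev, X[, v, drop = FALSE])
    f$coefficients
  }))
  multi <- cox_fit(tt, ev, X)$coefficients
  list(univariate = uni, multivariate = multi)
}
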