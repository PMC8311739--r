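# Risk scores from the pair signature, the AIC-optimal dichotomization
# cut-point, risk-group assignment, and time-dependent AUC evaluation.

#' Per-sample risk score from a pair signature
#'
#' `RiskScore(s) = sum_i beta_i * S_i(s)` over the signature pairs:
#' an exact weighted sum of 0/1 indicators, deterministic given the
#' model and the pair matrix.
#'
#' @param model a `SignatureModel`.
#' @param pm a `PairIndicatorMatrix` containing every model pair (a
#'   missing pair is a hard error: scores must never be silently partial).
#' @return named numeric vector of scores (one per sample).
#' @export
risk_score <- function(model, pm) {
  stopifnot(inherits(model, "SignatureModel"),
            inherits(pm, "PairIndicatorMatrix"))
  missing <- setdiff(model$pairs, rownames(pm$S))
  if (length(missing))
    stop("pairs missing from the indicator matrix: ",
         paste(missing, collapse = ", "))
  drop(crossprod(pm$S[model$pairs, , drop = FALSE], model$beta))
}

#' AIC-optimal risk-score cut-point
#'
#' Candidate cut-points are midpoints between consecutive unique scores
#' within the central quantile band; for each candidate a Cox model on
#' the dichotomized score is fitted and the candidate minimizing the AIC
#' wins (ties broken toward the smaller cut-point). When no candidate is
#' feasible the median split is returned, flagged. `method = "youden"`
#' instead maximizes sensitivity + specificity - 1 on the time-dependent
#' ROC at `horizon`.
#'
#' @param scores per-sample risk scores.
#' @param times,events survival data aligned with `scores`.
#' @param band quantile band for candidates (default 10th-90th
#'   percentile, which prevents degenerate tiny groups).
#' @param min_group minimum group size on each side of a candidate
#'   (default 10).
#' @param method `"aic"` (default) or `"youden"`.
#' @param horizon ROC horizon, required for `method = "youden"`.
#' @return list of class `cutpoint`: `cutpoint`, `method`, `fallback`,
#'   and `table` (candidate cut-points with their AIC, for inspection).
#' @export
aic_cutpoint <- function(scores, times, events, band = c(0.1, 0.9),
                         min_group = 10, method = c("aic", "youden"),
                         horizon = NULL) {
  method <- match.arg(method)
  stopifnot(length(scores) == length(times))
  if (method == "youden") {
    if (is.null(horizon)) stop("method = 'youden' needs a horizon")
    roc <- td_roc(times, events, scores, horizon)
    j <- roc$roc$tpr - roc$roc$fpr
    ok <- is.finite(roc$roc$threshold)
    best <- which(ok)[which.max(j[ok])]
    return(structure(list(cutpoint = roc$roc$threshold[best],
                          method = method, fallback = FALSE,
                          table = roc$roc), class = "cutpoint"))
  }
  u <- sort(unique(scores))
  cand <- (u[-1] + u[-length(u)]) / 2
  qb <- stats::quantile(scores, band)
  cand <- cand[cand >= qb[1] & cand <= qb[2]]
  cand <- cand[vapply(cand, function(cc) {
    g <- sum(scores > cc)
    g >= min_group && (length(scores) - g) >= min_group
  }, logical(1))]
  if (!length(cand)) {
    warning("no feasible cut-point candidates; falling back to the median")
    return(structure(list(cutpoint = stats::median(scores), method = method,
                          fallback = TRUE, table = NULL),
                     class = "cutpoint"))
  }
  # near-separation candidates trip the engine's "coefficient may be
  # infinite" warning; the scan only consumes the converged likelihood
  aic <- vapply(cand, function(cc)
    unname(suppressWarnings(
      cox_fast1(times, events, as.numeric(scores > cc)))["aic"]),
    numeric(1))
  best <- which(aic == min(aic))[1]     # ties -> smaller cut-point
  structure(list(cutpoint = cand[best], method = method, fallback = FALSE,
                 table = data.frame(cutpoint = cand, aic = aic)),
            class = "cutpoint")
}

#' Assign high/low risk groups at a cut-point
#' @param scores named risk scores.
#' @param cutpoint the cut-point c*; `high` iff score > c*.
#' @return data.frame of class `RiskAssignment`: `sample_id`, `score`,
#'   `group` (factor low/high).
#' @export
assign_risk_groups <- function(scores, cutpoint) {
  out <- data.frame(sample_id = names(scores), score = unname(scores),
                    group = factor(ifelse(scores > cutpoint, "high", "low"),
                                   levels = c("low", "high")),
                    stringsAsFactors = FALSE)
  class(out) <- c("RiskAssignment", "data.frame")
  attr(out, "cutpoint") <- cutpoint
  out
}

#' Time-dependent AUCs of the risk score and clinical comparators
#'
#' IPCW cumulative/dynamic AUC of the risk score at each horizon, plus
#' the same first-horizon AUC for each numeric-coded clinical comparator
#' covariate (age, sex, grade, stage when present).
#'
#' @param scores named per-sample risk scores.
#' @param clinical `ClinicalTable` (matched by sample ID).
#' @param horizons evaluation times in years (default 1, 3, 5).
#' @param comparators clinical columns to benchmark at the first horizon.
#' @param days_per_year conversion used when the clinical time unit is
#'   days (default 365.25).
#' @return list: `auc` (data.frame horizon/auc), `roc` (list of `td_roc`),
#'   `comparator_auc` (data.frame covariate/auc).
#' @export
evaluate_auc <- function(scores, clinical, horizons = c(1, 3, 5),
                         comparators = c("age", "sex", "grade", "stage"),
                         days_per_year = 365.25) {
  stopifnot(!is.null(names(scores)))
  idx <- match(clinical$sample_id, names(scores))
  ok <- !is.na(idx)
  cl <- clinical[ok, , drop = FALSE]
  sc <- scores[idx[ok]]
  unit <- attr(clinical, "time_unit")
  mult <- if (identical(unit, "days")) days_per_year else 1
  ht <- horizons * mult
  rocs <- lapply(ht, function(h) td_roc(cl$os_time, cl$os_event, sc, h))
  auc <- data.frame(horizon = horizons,
                    auc = vapply(rocs, function(r) r$auc, numeric(1)))
  comparators <- intersect(comparators, colnames(cl))
  comp <- data.frame(covariate = character(0), auc = numeric(0))
  if (length(comparators)) {
    comp <- do.call(rbind, lapply(comparators, function(v) {
      x <- as.numeric(cl[[v]])
      keep <- !is.na(x)
      data.frame(covariate = v,
                 auc = td_roc(cl$os_time[keep], cl$os_event[keep],
                              x[keep], ht[1])$auc)
    }))
  }
  list(auc = auc, roc = rocs, comparator_auc = comp)
}
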