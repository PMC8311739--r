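# Survival-statistics layer: Cox proportional hazards (Efron ties),
# Kaplan-Meier, log-rank, penalized Cox paths, and an IPCW
# cumulative/dynamic time-dependent ROC. Cox/KM/log-rank/lasso are
# delegated to the survival and glmnet engines; the time-dependent ROC is
# implemented here (no pre-installed package provides it).

#' Fit a Cox proportional-hazards model
#'
#' Efron tie handling, Wald p-values and confidence intervals (matching
#' forest-plot convention). Constant covariates are dropped with a warning
#' and reported with beta = 0, HR = 1. Monotone-likelihood (separation)
#' fits are flagged and their coefficients capped at +/- 15.
#'
#' @param times,events survival times and 0/1 event indicators.
#' @param x covariate vector or matrix (one column per covariate).
#' @param penalty optional ridge penalty (L2, `survival::ridge()` theta);
#'   0 = unpenalized.
#' @param conf_level Wald CI level (default 0.95).
#' @return object of class `cox_fit`: list with `coefficients`
#'   (data.frame: term, beta, se, hr, ci_low, ci_high, p), `loglik`
#'   (log partial likelihood at the MLE), `aic` (`2k - 2 logPL`), `n`,
#'   `n_events`, `converged`, `flagged`.
#' @export
cox_fit <- function(times, events, x, penalty = 0, conf_level = 0.95) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (length(times) != nrow(x) || length(events) != nrow(x))
    stop("times, events and covariate rows must align")
  if (sum(events) < 1) stop("need at least one event")
  if (any(!is.finite(x))) stop("covariates must be finite")
  const <- apply(x, 2, function(v) length(unique(v)) == 1L)
  dropped <- colnames(x)[const]
  if (any(const))
    warning("dropped constant covariates: ", paste(dropped, collapse = ", "))
  xk <- x[, !const, drop = FALSE]
  nd <- length(dropped)
  terms0 <- data.frame(term = dropped, beta = rep(0, nd),
                       se = rep(NA_real_, nd), hr = rep(1, nd),
                       ci_low = rep(NA_real_, nd),
                       ci_high = rep(NA_real_, nd), p = rep(NA_real_, nd),
                       stringsAsFactors = FALSE)
  if (ncol(xk) == 0L) {
    return(structure(list(coefficients = terms0, loglik = NA_real_,
                          aic = NA_real_, n = length(times),
                          n_events = sum(events), converged = TRUE,
                          flagged = character(0)), class = "cox_fit"))
  }
  df <- data.frame(.time = times, .event = events, xk, check.names = FALSE)
  preds <- paste0("`", colnames(xk), "`")
  rhs <- if (penalty > 0)
    paste0("survival::ridge(", paste(preds, collapse = ", "),
           ", theta = ", penalty, ")") else
             paste(preds, collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  environment(fml) <- environment()
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  flagged <- character(0)
  if (any(abs(beta) > 15)) {
    flagged <- colnames(xk)[abs(beta) > 15]
    beta <- pmin(pmax(beta, -15), 15)       # monotone likelihood cap
  }
  converged <- !any(grepl("did not converge|Ran out of iterations", warn))
  if (any(grepl("infinite|coefficient may be infinite", warn)))
    flagged <- unique(c(flagged, colnames(xk)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(term = colnames(xk), beta = unname(beta),
                    se = unname(se), hr = exp(unname(beta)),
                    ci_low = exp(unname(beta) - z * unname(se)),
                    ci_high = exp(unname(beta) + z * unname(se)),
                    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
                    stringsAsFactors = FALSE)
  tab <- rbind(tab, terms0)
  logpl <- fit$loglik[length(fit$loglik)]
  structure(list(coefficients = tab, loglik = logpl,
                 aic = 2 * ncol(xk) - 2 * logpl, n = length(times),
                 n_events = sum(events), converged = converged,
                 flagged = flagged, fit = fit), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit:", x$n, "subjects,", x$n_events, "events; AIC =",
      round(x$aic, 2), if (!x$converged) "(NOT converged)", "\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

# fast single-covariate Cox via survival::coxph.fit; returns beta, se, p,
# loglik at MLE, aic. Used by the univariate screen and cut-point scan.
cox_fast1 <- function(times, events, v) {
  y <- survival::Surv(as.numeric(times), as.numeric(events))
  fit <- survival::coxph.fit(matrix(as.numeric(v), ncol = 1), y,
                             strata = NULL,
                             offset = NULL, init = 0,
                             control = survival::coxph.control(),
                             weights = NULL, method = "efron",
                             rownames = NULL)
  beta <- fit$coefficients[1]
  se <- sqrt(fit$var[1, 1])
  logpl <- fit$loglik[length(fit$loglik)]
  c(beta = unname(beta), se = unname(se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    loglik = logpl, aic = 2 - 2 * logpl)
}

#' Kaplan-Meier survival estimate
#' @param times,events survival times and 0/1 event indicators.
#' @return data.frame of class `SurvivalCurve`: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (product-limit estimate).
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("need at least one subject")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    surv = sf$surv)
  class(out) <- c("SurvivalCurve", "data.frame")
  out
}

#' Two-group log-rank test
#' @param times,events survival data.
#' @param group two-level grouping (factor or vector); both groups must be
#'   non-empty.
#' @return list: `statistic` (chi-square, 1 df), `p`, `n` per group,
#'   `observed`, `expected` per group.
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) != 2)
    stop("logrank_test requires exactly 2 groups, got ", nlevels(group))
  if (any(table(group) == 0)) stop("a group has zero subjects")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group, rho = 0)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = as.vector(table(group)), observed = as.vector(sd$obs),
       expected = as.vector(sd$exp))
}

# censoring-distribution KM, evaluated with left limits G(u-)
.censor_km <- function(times, events) {
  sf <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  st <- sf$time[sf$n.event > 0]
  sv <- sf$surv[sf$n.event > 0]
  function(u, left = FALSE) {
    if (!length(st)) return(rep(1, length(u)))
    pos <- findInterval(u, st)
    if (left) {   # count censor times strictly below u
      at <- pos >= 1 & pos <= length(st)
      adj <- at & st[pmax(pos, 1)] == u
      pos[adj] <- pos[adj] - 1
    }
    ifelse(pos == 0, 1, sv[pmax(pos, 1)])
  }
}

#' Time-dependent ROC curve and AUC (cumulative/dynamic, IPCW)
#'
#' Cases at horizon t are subjects with an observed event at or before t;
#' controls are subjects still under observation beyond t. Censoring is
#' handled by inverse-probability-of-censoring weights from the
#' Kaplan-Meier estimate of the censoring distribution: a case observed
#' at time u gets weight 1/G(u-), controls get weight 1/G(t). The AUC is
#' the weighted Wilcoxon proportion with score ties counting 1/2; with no
#' censoring it reduces to the classical binary AUC for the
#' event-by-t labeling.
#'
#' @param times,events survival data.
#' @param score per-subject risk score (higher = higher risk).
#' @param horizon evaluation time t, inside the observed time range.
#' @return object of class `td_roc`: list with `horizon`, `auc`,
#'   `n_cases`, `n_controls`, and `roc` (data.frame `threshold`, `fpr`,
#'   `tpr`, from (0,0) to (1,1)).
#' @export
td_roc <- function(times, events, score, horizon) {
  stopifnot(length(times) == length(score))
  is_case <- times <= horizon & events == 1
  is_ctrl <- times > horizon
  if (!any(is_case)) stop("no cases at horizon t = ", horizon)
  if (!any(is_ctrl)) stop("no controls at horizon t = ", horizon)
  G <- .censor_km(times, events)
  w_case <- 1 / G(times[is_case], left = TRUE)
  if (any(!is.finite(w_case))) {
    warning("dropped ", sum(!is.finite(w_case)),
            " cases with zero censoring-survival weight")
    keep <- is.finite(w_case)
    w_case <- w_case[keep]
    sc_case <- score[is_case][keep]
  } else sc_case <- score[is_case]
  sc_ctrl <- score[is_ctrl]
  n_ctrl <- length(sc_ctrl)
  cmp <- outer(sc_case, sc_ctrl, ">") + 0.5 * outer(sc_case, sc_ctrl, "==")
  auc <- sum(w_case * rowSums(cmp)) / (sum(w_case) * n_ctrl)
  thr <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(cc) sum(w_case[sc_case > cc]) / sum(w_case),
                numeric(1))
  fpr <- vapply(thr, function(cc) mean(sc_ctrl > cc), numeric(1))
  structure(list(horizon = horizon, auc = auc, n_cases = length(sc_case),
                 n_controls = n_ctrl,
                 roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat("time-dependent ROC at t =", x$horizon, ": AUC =", round(x$auc, 4),
      "(", x$n_cases, "cases /", x$n_controls, "controls )\n")
  invisible(x)
}

#' L1-penalized Cox coefficient path
#'
#' Thin wrapper over the glmnet coordinate-descent engine (covariates
#' standardized internally; reported coefficients are on the original
#' scale). At the head of the default grid (`lambda >= lambda_max`) all
#' coefficients are zero; at `lambda = 0` the fit matches the unpenalized
#' partial-likelihood maximizer.
#'
#' @param times,events survival data.
#' @param X samples-by-covariates matrix (>= 2 columns).
#' @param lambda optional decreasing penalty grid; default: glmnet's
#'   log-spaced 100-step grid from lambda_max.
#' @param nlambda grid length when `lambda` is NULL.
#' @return list: `lambda` (grid), `beta` (covariates x grid matrix),
#'   `lambda_max`, and the underlying `fit`.
#' @export
lasso_cox_path <- function(times, events, X, lambda = NULL, nlambda = 100) {
  X <- as.matrix(X)
  fit <- glmnet::glmnet(X, survival::Surv(times, events), family = "cox",
                        lambda = lambda, nlambda = nlambda,
                        standardize = TRUE, thresh = 1e-12)
  list(lambda = fit$lambda, beta = as.matrix(fit$beta),
       lambda_max = fit$lambda[1], fit = fit)
}

#' Cross-validated Lasso-Cox (single run)
#'
#' @param times,events survival data.
#' @param X samples-by-covariates matrix.
#' @param folds number of CV folds (default 10).
#' @param foldid optional explicit fold assignment (overrides `folds`).
#' @param rule `"min"` = deviance-minimizing lambda (default);
#'   `"1se"` = one-standard-error rule.
#' @return list: `lambda` (chosen), `selected` (names of
#'   nonzero-coefficient covariates), `beta` (nonzero coefficients), `cv`
#'   (the cv.glmnet object).
#' @export
cv_lasso_cox <- function(times, events, X, folds = 10, foldid = NULL,
                         rule = c("min", "1se")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  y <- survival::Surv(times, events)
  cv <- if (is.null(foldid))
    glmnet::cv.glmnet(X, y, family = "cox", type.measure = "deviance",
                      nfolds = folds) else
    glmnet::cv.glmnet(X, y, family = "cox", type.measure = "deviance",
                      foldid = foldid)
  s <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.matrix(stats::coef(cv, s = s))
  nz <- cf[, 1] != 0
  list(lambda = s, selected = rownames(cf)[nz], beta = cf[nz, 1], cv = cv)
}
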