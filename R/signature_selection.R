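# Signature selection: univariate Cox screen over pair indicators,
# repeated cross-validated Lasso-Cox frequency selection, then
# bidirectional stepwise multivariate Cox (AIC).

# inner-join pair matrix samples with clinical rows; mismatches logged
align_samples <- function(pm, clinical) {
  stopifnot(inherits(pm, "PairIndicatorMatrix"),
            inherits(clinical, "ClinicalTable") || is.data.frame(clinical))
  common <- intersect(colnames(pm$S), clinical$sample_id)
  drop_pm <- ncol(pm$S) - length(common)
  drop_cl <- nrow(clinical) - length(common)
  if (!length(common)) stop("no samples shared between pairs and clinical")
  if (drop_pm > 0 || drop_cl > 0)
    message("sample alignment dropped ", drop_pm, " pair-matrix and ",
            drop_cl, " clinical samples")
  list(pm = subset_pairs(pm, samples = common),
       clinical = clinical[match(common, clinical$sample_id), ,
                           drop = FALSE])
}

#' Univariate Cox screen over pair indicators
#'
#' One single-covariate Cox fit per pair indicator; pairs with Wald
#' p below the threshold survive. Constant indicators (which should not
#' occur after the prevalence filter) are skipped with a warning.
#'
#' @param pm `PairIndicatorMatrix`.
#' @param clinical `ClinicalTable`; samples are inner-joined by ID.
#' @param p_threshold Wald p threshold (default 0.01, strict `<`).
#' @return list of class `selection_stage`: `table` (pair_id, beta, se,
#'   p, keep), `kept` (surviving pair IDs), `n_in`, `n_out`.
#' @export
univariate_screen <- function(pm, clinical, p_threshold = 0.01) {
  al <- align_samples(pm, clinical)
  S <- al$pm$S
  tt <- al$clinical$os_time
  ev <- al$clinical$os_event
  res <- matrix(NA_real_, nrow(S), 3,
                dimnames = list(rownames(S), c("beta", "se", "p")))
  skipped <- 0L
  for (i in seq_len(nrow(S))) {
    v <- S[i, ]
    if (length(unique(v)) == 1L) { skipped <- skipped + 1L; next }
    f <- cox_fast1(tt, ev, v)
    res[i, ] <- f[c("beta", "se", "p")]
  }
  if (skipped > 0)
    warning("skipped ", skipped, " constant pair indicators")
  keep <- !is.na(res[, "p"]) & res[, "p"] < p_threshold
  if (!any(keep))
    stop("no pairs survive the univariate screen at p < ", p_threshold,
         "; consider relaxing the threshold")
  structure(list(table = data.frame(pair_id = rownames(S),
                                    beta = res[, "beta"], se = res[, "se"],
                                    p = res[, "p"], keep = keep,
                                    row.names = NULL,
                                    stringsAsFactors = FALSE),
                 kept = rownames(S)[keep], n_in = nrow(S),
                 n_out = sum(keep)),
            class = "selection_stage")
}

#' Repeated cross-validated Lasso-Cox frequency selection
#'
#' Each repetition redraws its own k-fold partition (per-repetition RNG
#' streams spawned from the master seed), picks the deviance-minimizing
#' lambda, and credits every pair with a nonzero coefficient at that
#' lambda. Pairs selected in strictly more than `freq_threshold`
#' repetitions survive. Presets: the reference protocol is 1000
#' repetitions / threshold 100; a 100/10 scaling preserves the 10:1 ratio
#' for fast runs.
#'
#' @param pm `PairIndicatorMatrix` restricted to univariate survivors.
#' @param clinical `ClinicalTable`.
#' @param repetitions number of CV repetitions (default 1000).
#' @param folds CV folds per repetition (default 10).
#' @param freq_threshold keep pairs with frequency strictly greater than
#'   this (default 100).
#' @param seed master seed; identical seeds give identical frequency
#'   tables.
#' @param rule lambda rule passed to [cv_lasso_cox()].
#' @return list of class `selection_stage`: `frequency` (named counts),
#'   `kept`, `n_empty` (repetitions selecting no pair), `repetitions`,
#'   `seed`.
#' @export
repeated_lasso <- function(pm, clinical, repetitions = 1000, folds = 10,
                           freq_threshold = 100, seed = 1,
                           rule = c("min", "1se")) {
  rule <- match.arg(rule)
  al <- align_samples(pm, clinical)
  if (nrow(al$pm$S) < 2)
    stop("repeated_lasso needs >= 2 candidate pairs")
  X <- t(al$pm$S)
  tt <- al$clinical$os_time
  ev <- al$clinical$os_event
  n <- nrow(X)
  set.seed(seed %% .Machine$integer.max)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, repetitions)
  freq <- stats::setNames(integer(ncol(X)), colnames(X))
  n_empty <- 0L
  for (r in seq_len(repetitions)) {
    set.seed(rep_seeds[r])
    foldid <- sample(rep_len(seq_len(folds), n))
    sel <- cv_lasso_cox(tt, ev, X, foldid = foldid, rule = rule)$selected
    if (!length(sel)) n_empty <- n_empty + 1L else
      freq[sel] <- freq[sel] + 1L
  }
  if (n_empty == repetitions)
    stop("every repetition selected an empty model")
  kept <- names(freq)[freq > freq_threshold]
  structure(list(frequency = freq, kept = kept, n_empty = n_empty,
                 repetitions = repetitions, folds = folds,
                 freq_threshold = freq_threshold, seed = seed,
                 n_in = ncol(X), n_out = length(kept)),
            class = "selection_stage")
}

#' Stepwise multivariate Cox model over selected pairs
#'
#' Bidirectional stepwise selection minimizing AIC, starting from the
#' full model (single add/drop moves until no move lowers the AIC). If
#' the full model does not converge, falls back to forward-only selection
#' from the null model (flagged). Also emits univariate and multivariate
#' HR/CI tables for all candidate pairs.
#'
#' @param pm `PairIndicatorMatrix` restricted to the lasso survivors.
#' @param clinical `ClinicalTable`.
#' @return object of class `SignatureModel`: list with `pairs` (IDs),
#'   `beta` (named multivariate coefficients), `k`, `aic`, `cutpoint`
#'   (NA until set by the risk model), `tables` (univariate /
#'   multivariate candidate tables), `fallback_forward` flag.
#' @export
stepwise_multivariate <- function(pm, clinical) {
  al <- align_samples(pm, clinical)
  S <- al$pm$S
  tt <- al$clinical$os_time
  ev <- al$clinical$os_event
  ids <- rownames(S)
  vars <- make.names(ids)                    # syntactic for formulas
  df <- data.frame(t(S))
  colnames(df) <- vars
  df$.time <- tt; df$.event <- ev
  uni <- do.call(rbind, lapply(ids, function(pid) {
    f <- cox_fit(tt, ev, matrix(S[pid, ], ncol = 1,
                                dimnames = list(NULL, pid)))
    cbind(pair_id = pid, f$coefficients[1, -1])
  }))
  full_fml <- stats::as.formula(
    paste("survival::Surv(.time, .event) ~", paste(vars, collapse = " + ")))
  environment(full_fml) <- environment()
  fallback <- FALSE
  full <- tryCatch(
    survival::coxph(full_fml, data = df, ties = "efron"),
    warning = function(w) w, error = function(e) e)
  bad_full <- inherits(full, "condition") &&
    grepl("did not converge|Ran out of iterations",
          conditionMessage(full))
  if (inherits(full, "condition") && !bad_full)
    full <- suppressWarnings(survival::coxph(full_fml, data = df,
                                             ties = "efron"))
  null_fml <- stats::as.formula("survival::Surv(.time, .event) ~ 1")
  environment(null_fml) <- environment()
  if (bad_full) {
    fallback <- TRUE
    start <- survival::coxph(null_fml, data = df, ties = "efron")
    sel <- suppressWarnings(stats::step(
      start, scope = list(lower = null_fml, upper = full_fml),
      direction = "forward", trace = 0))
  } else {
    sel <- suppressWarnings(stats::step(
      full, scope = list(lower = null_fml, upper = full_fml),
      direction = "both", trace = 0))
  }
  cf <- stats::coef(sel)
  if (is.null(cf) || !length(cf)) {
    # AIC preferred the empty model; keep the single best univariate pair
    best <- ids[which.min(uni$p)]
    warning("stepwise selection emptied the model; keeping best ",
            "univariate pair ", best)
    f1 <- cox_fit(tt, ev, matrix(S[best, ], ncol = 1,
                                 dimnames = list(NULL, best)))
    beta <- stats::setNames(f1$coefficients$beta[1], best)
    aic <- f1$aic
    multi_tab <- cbind(pair_id = best, f1$coefficients[1, -1])
  } else {
    beta <- stats::setNames(unname(cf), ids[match(names(cf), vars)])
    aic <- stats::extractAIC(sel)[2]
    s <- summary(sel)
    multi_tab <- data.frame(pair_id = ids[match(rownames(s$coefficients),
                                                vars)],
                            beta = s$coefficients[, "coef"],
                            se = s$coefficients[, "se(coef)"],
                            hr = s$coefficients[, "exp(coef)"],
                            ci_low = s$conf.int[, "lower .95"],
                            ci_high = s$conf.int[, "upper .95"],
                            p = s$coefficients[, "Pr(>|z|)"],
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(pairs = names(beta), beta = beta, k = length(beta),
                 aic = aic, cutpoint = NA_real_,
                 tables = list(univariate = uni, multivariate = multi_tab),
                 fallback_forward = fallback),
            class = "SignatureModel")
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat("Pair signature:", x$k, "pairs; AIC =", round(x$aic, 2),
      "; cut-point =",
      if (is.na(x$cutpoint)) "unset" else round(x$cutpoint, 4), "\n")
  print(data.frame(pair = x$pairs, beta = round(unname(x$beta), 4)),
        row.names = FALSE)
  invisible(x)
}
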