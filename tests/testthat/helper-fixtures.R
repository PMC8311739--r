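# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# expression container from a plain matrix (default: all tumor samples)
make_expr <- function(values, conditions = NULL, biotypes = NULL) {
  if (is.null(conditions))
    conditions <- stats::setNames(rep("tumor", ncol(values)),
                                  colnames(values))
  expression_matrix(values, conditions, biotypes)
}

# expression matrix whose log2(x+1) values equal `logvals` exactly
expr_from_log <- function(logvals, conditions = NULL, biotypes = NULL) {
  make_expr(2^logvals - 1, conditions, biotypes)
}

# pair-indicator container from a handmade binary matrix (rownames "A|B")
pm_from_S <- function(S) {
  parts <- strsplit(rownames(S), "|", fixed = TRUE)
  structure(list(S = S,
                 pairs = data.frame(a = vapply(parts, `[`, "", 1),
                                    b = vapply(parts, `[`, "", 2),
                                    pair_id = rownames(S),
                                    stringsAsFactors = FALSE),
                 freq1 = rowMeans(S)),
            class = "PairIndicatorMatrix")
}

# minimal clinical table
make_clinical <- function(sample_id, os_time, os_event, ...) {
  out <- data.frame(sample_id = sample_id, os_time = os_time,
                    os_event = os_event, ..., stringsAsFactors = FALSE)
  attr(out, "time_unit") <- "years"
  class(out) <- c("ClinicalTable", "data.frame")
  out
}

# small-but-structured simulation config for fast end-to-end tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(n_tumor = 150, n_normal = 15, n_lnc = 60,
             n_immune_genes = 40, n_other_genes = 40,
             n_coexpressed_lnc = 30, n_de_lnc = 24, n_planted_pairs = 5,
             seed = seed, ...)
}

# independent Efron log partial likelihood evaluation (test oracle):
# direct sum over event times with the Efron correction for ties
efron_loglik <- function(beta, times, events, x) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    d <- length(D)
    sumR <- sum(exp(eta[R]))
    sumD <- sum(exp(eta[D]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sumR - (l / d) * sumD)
  }
  ll
}
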