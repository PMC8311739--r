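# The 0-or-1 pair-indicator matrix: for an (A, B) gene pair and sample s,
# S = 1 iff expression of A exceeds that of B within s (ties score 0).
# The encoding is normalization-free: any strictly increasing per-sample
# transform of expression leaves S unchanged.

#' Build the pair-indicator matrix over a gene set
#'
#' All C(m, 2) unordered pairs of the usable genes, in canonical
#' lexicographic orientation (A < B as strings). `S[pair, s] = 1` iff
#' `expr(A, s) > expr(B, s)`; ties give 0. Genes absent from the matrix
#' are excluded first with a logged count (pairs whose members have no
#' expression values carry no information).
#'
#' @param expr an `ExpressionMatrix` or a plain genes-by-samples numeric
#'   matrix.
#' @param genes gene symbols to pair (>= 2 must be present).
#' @return an object of class `PairIndicatorMatrix`: list with `S`
#'   (binary pairs x samples matrix, rownames `A|B`), `pairs`
#'   (data.frame `a`, `b`, `pair_id`), `freq1` (per-pair fraction of 1s).
#' @export
build_pairs <- function(expr, genes) {
  vals <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  stopifnot(is.matrix(vals))
  genes <- unique(toupper(genes))
  absent <- setdiff(genes, rownames(vals))
  if (length(absent))
    message("excluded ", length(absent),
            " genes with no expression values from pairing")
  genes <- sort(intersect(genes, rownames(vals)))
  if (length(genes) < 2)
    stop("need >= 2 genes with expression values to build pairs")
  idx <- t(utils::combn(length(genes), 2L))
  a <- genes[idx[, 1]]; b <- genes[idx[, 2]]
  S <- (vals[a, , drop = FALSE] > vals[b, , drop = FALSE]) + 0L
  rownames(S) <- paste(a, b, sep = "|")
  pairs <- data.frame(a = a, b = b, pair_id = rownames(S),
                      stringsAsFactors = FALSE)
  structure(list(S = S, pairs = pairs, freq1 = rowMeans(S)),
            class = "PairIndicatorMatrix")
}

#' @export
print.PairIndicatorMatrix <- function(x, ...) {
  cat("PairIndicatorMatrix:", nrow(x$S), "pairs x", ncol(x$S), "samples\n")
  invisible(x)
}

#' Prevalence filter on pair indicators
#'
#' Keeps a pair only when both its 0s and its 1s each cover at least
#' `min_frac` of the samples, i.e. `min_frac <= freq1 <= 1 - min_frac`
#' (boundaries inclusive). Near-constant indicators carry no prognostic
#' contrast and would destabilize the Cox fits.
#'
#' @param pm a `PairIndicatorMatrix`.
#' @param min_frac minimum prevalence of each indicator value
#'   (default 0.2).
#' @return the filtered `PairIndicatorMatrix`.
#' @export
prevalence_filter <- function(pm, min_frac = 0.2) {
  stopifnot(inherits(pm, "PairIndicatorMatrix"))
  eps <- 1e-12
  keep <- pm$freq1 >= min_frac - eps & pm$freq1 <= 1 - min_frac + eps
  if (!any(keep))
    stop("prevalence filter removed every pair; review min_frac = ",
         min_frac)
  subset_pairs(pm, pairs = rownames(pm$S)[keep])
}

#' Subset a pair-indicator matrix by pairs and/or samples
#' @param pm a `PairIndicatorMatrix`.
#' @param pairs pair IDs (`A|B`) to keep; default all.
#' @param samples sample IDs to keep; default all. `freq1` is recomputed
#'   on the retained samples.
#' @return the subset `PairIndicatorMatrix`.
#' @export
subset_pairs <- function(pm, pairs = NULL, samples = NULL) {
  stopifnot(inherits(pm, "PairIndicatorMatrix"))
  if (is.null(pairs)) pairs <- rownames(pm$S)
  if (is.null(samples)) samples <- colnames(pm$S)
  S <- pm$S[pairs, samples, drop = FALSE]
  structure(list(S = S,
                 pairs = pm$pairs[match(pairs, pm$pairs$pair_id), ,
                                  drop = FALSE],
                 freq1 = rowMeans(S)),
            class = "PairIndicatorMatrix")
}

#' Write a pair-indicator matrix to TSV
#' @param pm a `PairIndicatorMatrix`.
#' @param path output path; columns: pair_id, freq1, one column per sample.
#' @export
write_pairs <- function(pm, path) {
  stopifnot(inherits(pm, "PairIndicatorMatrix"))
  df <- data.frame(pair_id = rownames(pm$S), freq1 = pm$freq1, pm$S,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
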