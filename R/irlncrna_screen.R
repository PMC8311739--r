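# Stage 1 screens: immune-related lncRNAs by coexpression with immune
# genes, then differential expression between tumor and normal tissue.

#' Screen lncRNAs for coexpression with immune genes
#'
#' Pearson correlation on the `log2(x + 1)` scale between every
#' lncRNA-biotype gene and every immune-list gene present in the matrix.
#' A lncRNA passes when any immune partner satisfies both thresholds; the
#' reported partner is the one with the strongest correlation. P-values
#' come from the t-distribution transform of r with n - 2 degrees of
#' freedom and are deliberately not multiplicity-adjusted (the screen is a
#' raw-p filter).
#'
#' @param expr `ExpressionMatrix` with gene biotypes set.
#' @param immune_genes character vector of immune-related gene symbols.
#' @param r_threshold correlation threshold (default 0.6, strict `>`).
#' @param p_threshold p-value threshold (default 0.001, strict `<`).
#' @param mode `"absolute"` screens on |r| (default); `"positive"` on
#'   signed r.
#' @param samples `"all"` (default) or `"tumor"`: which samples enter the
#'   correlation.
#' @return data.frame with one row per testable lncRNA: `lncrna`,
#'   `partner`, `r`, `p`, `passed`. Constant-expression genes are skipped
#'   with a logged count.
#' @export
screen_irlncrnas <- function(expr, immune_genes, r_threshold = 0.6,
                             p_threshold = 0.001,
                             mode = c("absolute", "positive"),
                             samples = c("all", "tumor")) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  mode <- match.arg(mode)
  samples <- match.arg(samples)
  keep_s <- if (samples == "tumor")
    names(expr$sample_condition)[expr$sample_condition == "tumor"] else
      colnames(expr$values)
  lnc <- rownames(expr$values)[!is.na(expr$gene_biotype) &
                                 tolower(expr$gene_biotype) == "lncrna"]
  imm <- intersect(toupper(immune_genes), rownames(expr$values))
  if (!length(lnc)) stop("no lncRNA-biotype genes in the expression matrix")
  if (!length(imm)) stop("no immune-list genes found in the expression matrix")
  X <- log2p1(expr$values[, keep_s, drop = FALSE])
  n <- ncol(X)
  if (n < 3) stop("need >= 3 samples for a correlation p-value")
  sd_l <- apply(X[lnc, , drop = FALSE], 1, stats::sd)
  sd_i <- apply(X[imm, , drop = FALSE], 1, stats::sd)
  if (any(sd_l == 0) || any(sd_i == 0))
    message("skipped ", sum(sd_l == 0), " constant lncRNAs and ",
            sum(sd_i == 0), " constant immune genes")
  lnc <- lnc[sd_l > 0]; imm <- imm[sd_i > 0]
  if (!length(lnc) || !length(imm))
    stop("no non-constant genes left to correlate")
  R <- stats::cor(t(X[lnc, , drop = FALSE]), t(X[imm, , drop = FALSE]))
  pick <- if (mode == "absolute") abs(R) else R
  best <- max.col(pick, ties.method = "first")
  r <- R[cbind(seq_along(lnc), best)]
  r_eff <- pmin(pmax(r, -1), 1)
  tt <- abs(r_eff) * sqrt((n - 2) / pmax(1 - r_eff^2, .Machine$double.eps))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  crit <- if (mode == "absolute") abs(r) else r
  passed <- crit > r_threshold & p < p_threshold
  data.frame(lncrna = lnc, partner = imm[best], r = r, p = p,
             passed = passed, stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential-expression screen between tumor and normal samples
#'
#' logFC is the difference of mean `log2(x + 1)` expression (tumor minus
#' normal). The default test is the Wilcoxon rank-sum test per gene;
#' `method = "limma"` instead fits the limma linear model with empirical
#' Bayes moderation on the log scale. P-values are BH-adjusted over the
#' tested genes. A gene passes when `|logFC| > lfc_threshold` (strict) and
#' `FDR < fdr_threshold` (strict).
#'
#' @param expr `ExpressionMatrix` with tumor and normal samples.
#' @param genes genes to test (default: all rows); the pipeline passes the
#'   screened irlncRNA set so the BH adjustment runs over those only.
#' @param lfc_threshold log2 fold-change threshold (default 1).
#' @param fdr_threshold BH-adjusted p threshold (default 0.05).
#' @param method `"wilcoxon"` (default) or `"limma"`.
#' @return data.frame: `gene`, `logFC`, `p`, `fdr`, `direction`
#'   (up/down/none by sign of logFC), `passed`.
#' @export
de_screen <- function(expr, genes = NULL, lfc_threshold = 1,
                      fdr_threshold = 0.05,
                      method = c("wilcoxon", "limma")) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  method <- match.arg(method)
  if (is.null(genes)) genes <- rownames(expr$values)
  genes <- intersect(genes, rownames(expr$values))
  if (!length(genes)) stop("none of the requested genes are in the matrix")
  tum <- expr$sample_condition == "tumor"
  if (sum(tum) < 2 || sum(!tum) < 2)
    stop("need >= 2 tumor and >= 2 normal samples for the DE screen")
  X <- log2p1(expr$values[genes, , drop = FALSE])
  logfc <- rowMeans(X[, tum, drop = FALSE]) -
    rowMeans(X[, !tum, drop = FALSE])
  if (method == "wilcoxon") {
    p <- apply(X, 1, function(v)
      suppressWarnings(stats::wilcox.test(v[tum], v[!tum],
                                          exact = FALSE)$p.value))
  } else {
    if (!requireNamespace("limma", quietly = TRUE))
      stop("method = 'limma' requires the limma package")
    design <- cbind(intercept = 1, tumor = as.numeric(tum))
    fit <- limma::eBayes(limma::lmFit(X, design))
    p <- fit$p.value[, "tumor"]
  }
  p[is.na(p)] <- 1
  fdr <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(logfc > 0, "up", ifelse(logfc < 0, "down", "none"))
  data.frame(gene = genes, logFC = logfc, p = p, fdr = fdr,
             direction = direction,
             passed = abs(logfc) > lfc_threshold & fdr < fdr_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
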