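# Associate the risk groups / continuous risk score with externally
# computed per-sample tables: immune-infiltration estimates (deconvolution
# outputs are consumed, never recomputed), immune-checkpoint gene
# expression, and predicted drug IC50 values.

#' Read a feature-by-sample table (long or wide)
#'
#' Accepts either the aggregate deconvolution layout (`cell_type` and
#' `method` id columns followed by one column per sample), a generic wide
#' matrix (first column = feature id, remaining columns = samples), or an
#' already-long table with columns feature_id/sample_id/value.
#'
#' @param path TSV file (gzip accepted).
#' @param source tag for the values: `"infiltration"`, `"ici_gene"` or
#'   `"ic50"`.
#' @return long data.frame: `feature_id`, `sample_id`, `value`, `source`
#'   (plus `cell_type`/`method` for the deconvolution layout).
#' @export
read_feature_table <- function(path, source = c("infiltration", "ici_gene",
                                                "ic50")) {
  source <- match.arg(source)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  cn <- tolower(colnames(dt))
  if (all(c("feature_id", "sample_id", "value") %in% cn)) {
    out <- dt[, match(c("feature_id", "sample_id", "value"), cn),
              drop = FALSE]
    colnames(out) <- c("feature_id", "sample_id", "value")
    if ("cell_type" %in% cn) out$cell_type <- dt[[which(cn == "cell_type")]]
    if ("method" %in% cn) out$method <- dt[[which(cn == "method")]]
  } else if (all(c("cell_type", "method") %in% cn)) {
    idc <- match(c("cell_type", "method"), cn)
    samp <- setdiff(seq_along(cn), idc)
    out <- data.frame(
      feature_id = rep(paste(dt[[idc[1]]], dt[[idc[2]]], sep = "_"),
                       times = length(samp)),
      cell_type = rep(dt[[idc[1]]], times = length(samp)),
      method = rep(dt[[idc[2]]], times = length(samp)),
      sample_id = rep(colnames(dt)[samp], each = nrow(dt)),
      value = unlist(dt[, samp, drop = FALSE], use.names = FALSE),
      stringsAsFactors = FALSE)
  } else {
    samp <- seq_along(cn)[-1]
    out <- data.frame(
      feature_id = rep(as.character(dt[[1]]), times = length(samp)),
      sample_id = rep(colnames(dt)[samp], each = nrow(dt)),
      value = unlist(dt[, samp, drop = FALSE], use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  out$value <- as.numeric(out$value)
  out$source <- source
  out
}

#' Rank-sum tests of features between risk groups
#'
#' Per feature, a two-sided Mann-Whitney test between the high- and
#' low-risk groups. Direction is the sign of the high-minus-low median
#' difference. Raw p-values are thresholded at `alpha` (per protocol);
#' a BH-adjusted column is emitted alongside for transparency. For
#' deconvolution tables (with `cell_type`/`method` columns) a `consensus`
#' flag marks cell types whose significant directions agree across >= 2
#' methods.
#'
#' @param table long feature table (see [read_feature_table()]).
#' @param assignment a `RiskAssignment`.
#' @param alpha raw-p significance threshold (default 0.05).
#' @param min_per_group minimum samples per group per feature (default 5);
#'   features below it are skipped with a logged count.
#' @return data.frame of class `AssociationTable`: feature_id, test,
#'   statistic, p, p_adj, direction, flagged, n_high, n_low (+ cell_type,
#'   method, consensus when applicable).
#' @export
group_feature_tests <- function(table, assignment, alpha = 0.05,
                                min_per_group = 5) {
  stopifnot(inherits(assignment, "RiskAssignment"))
  m <- merge(table, as.data.frame(assignment)[, c("sample_id", "group")],
             by = "sample_id")
  feats <- unique(m$feature_id)
  skipped <- 0L
  rows <- lapply(feats, function(f) {
    sub <- m[m$feature_id == f, ]
    hi <- sub$value[sub$group == "high"]
    lo <- sub$value[sub$group == "low"]
    if (length(hi) < min_per_group || length(lo) < min_per_group) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    wt <- suppressWarnings(stats::wilcox.test(hi, lo, exact = FALSE))
    md <- stats::median(hi) - stats::median(lo)
    out <- data.frame(feature_id = f, test = "wilcoxon rank-sum",
                      statistic = unname(wt$statistic), p = wt$p.value,
                      direction = if (md > 0) "higher in high-risk"
                      else if (md < 0) "lower in high-risk" else "none",
                      n_high = length(hi), n_low = length(lo),
                      stringsAsFactors = FALSE)
    if ("cell_type" %in% colnames(sub)) {
      out$cell_type <- sub$cell_type[1]
      out$method <- sub$method[1]
    }
    out
  })
  if (skipped > 0)
    message("skipped ", skipped, " features with insufficient group overlap")
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no feature had enough samples in both groups")
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$flagged <- res$p < alpha
  if ("cell_type" %in% colnames(res)) {
    res$consensus <- vapply(seq_len(nrow(res)), function(i) {
      same <- res$cell_type == res$cell_type[i] & res$flagged &
        res$direction == res$direction[i]
      res$flagged[i] && length(unique(res$method[same])) >= 2
    }, logical(1))
  }
  class(res) <- c("AssociationTable", "data.frame")
  res
}

#' Spearman correlation of features with the continuous risk score
#'
#' Per feature, the tie-corrected Spearman rank correlation (and its
#' asymptotic p-value) against the risk score; results are sorted by rho,
#' ready for lollipop-style displays. Constant features are skipped with
#' a warning.
#'
#' @param table long feature table.
#' @param scores named per-sample risk scores.
#' @param min_pairs minimum paired observations per feature (default 5).
#' @return data.frame of class `AssociationTable`: feature_id, rho, p, n.
#' @export
spearman_risk_correlation <- function(table, scores, min_pairs = 5) {
  stopifnot(!is.null(names(scores)))
  m <- table[table$sample_id %in% names(scores), , drop = FALSE]
  m$score <- scores[m$sample_id]
  feats <- unique(m$feature_id)
  skipped <- 0L
  rows <- lapply(feats, function(f) {
    sub <- m[m$feature_id == f, ]
    sub <- sub[is.finite(sub$value) & is.finite(sub$score), ]
    if (nrow(sub) < min_pairs) return(NULL)
    if (stats::sd(sub$value) == 0) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    ct <- suppressWarnings(stats::cor.test(sub$value, sub$score,
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(feature_id = f, rho = unname(ct$estimate), p = ct$p.value,
               n = nrow(sub), stringsAsFactors = FALSE)
  })
  if (skipped > 0)
    warning("skipped ", skipped, " constant features (rho undefined)")
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no feature had enough paired observations")
  res <- res[order(res$rho, decreasing = TRUE), ]
  rownames(res) <- NULL
  class(res) <- c("AssociationTable", "data.frame")
  res
}
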