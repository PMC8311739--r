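# Readers/writers for every external format the pipeline touches, plus the
# shared expression-matrix container used by all downstream stages.

#' Construct an expression-matrix container
#'
#' The container bundles a non-negative genes-by-samples abundance matrix
#' (FPKM-like units, taken as-is; all downstream log transforms use
#' `log2(x + 1)`) with a tumor/normal condition label per sample and an
#' optional gene biotype map. Gene and sample identifiers must be unique;
#' gene symbols are case-normalized to upper case.
#'
#' @param values numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns (colnames = sample IDs). Must be finite and >= 0.
#' @param sample_condition named character vector mapping every sample ID
#'   to `"tumor"` or `"normal"`.
#' @param gene_biotype optional named character vector mapping gene symbols
#'   to biotype strings (e.g. `"lncRNA"`, `"protein_coding"`). Genes absent
#'   from the map get `NA`.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values`, `sample_condition`, `gene_biotype`.
#' @export
expression_matrix <- function(values, sample_condition, gene_biotype = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))])[1:5],
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))])[1:5],
               collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value for gene ", rownames(values)[bad[1]],
         ", sample ", colnames(values)[bad[2]])
  }
  sample_condition <- .check_conditions(sample_condition, colnames(values))
  bt <- rep(NA_character_, nrow(values))
  names(bt) <- rownames(values)
  if (!is.null(gene_biotype)) {
    names(gene_biotype) <- toupper(names(gene_biotype))
    hit <- intersect(names(bt), names(gene_biotype))
    bt[hit] <- unname(gene_biotype[hit])
  }
  structure(list(values = values, sample_condition = sample_condition,
                 gene_biotype = bt),
            class = "ExpressionMatrix")
}

.check_conditions <- function(cond, samples) {
  if (is.null(names(cond))) stop("sample conditions must be named by sample ID")
  cond <- stats::setNames(tolower(as.character(cond)), names(cond))
  missing <- setdiff(samples, names(cond))
  if (length(missing))
    stop("samples missing from condition map: ",
         paste(utils::head(missing, 5), collapse = ", "))
  cond <- cond[samples]
  bad <- !cond %in% c("tumor", "normal")
  if (any(bad))
    stop("condition labels must be 'tumor' or 'normal'; offending samples: ",
         paste(utils::head(samples[bad], 5), collapse = ", "))
  cond
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", sum(x$sample_condition == "tumor"), "tumor /",
      sum(x$sample_condition == "normal"), "normal )\n")
  nb <- sum(!is.na(x$gene_biotype))
  cat("  biotype annotated for", nb, "genes\n")
  invisible(x)
}

#' Read a tab-separated expression matrix
#'
#' First column holds gene symbols, the header holds sample IDs. Duplicate
#' gene rows are collapsed by their mean (order-independent; the collapse is
#' reported via `message()`). Values must be non-negative abundances.
#' Gzipped files are accepted.
#'
#' @param path path to the TSV matrix.
#' @param condition_map_path path to a two-column TSV (sample ID, condition
#'   `tumor`/`normal`); every sample in the matrix must appear here.
#' @return an [expression_matrix()] object (without biotypes; see
#'   [set_gene_biotypes()]).
#' @export
read_expression <- function(path, condition_map_path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  if (ncol(dt) < 2)
    stop("malformed expression file (need gene column + >=1 sample): ", path)
  genes <- toupper(as.character(dt[[1]]))
  vals <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stop("non-numeric or missing expression values in ", path)
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value for gene ", genes[bad[1]],
         ", sample ", colnames(vals)[bad[2]])
  }
  if (anyDuplicated(genes)) {
    ndup <- sum(duplicated(genes))
    sums <- rowsum(vals, group = genes)          # sorts by gene symbol
    cnt <- as.integer(table(genes))              # table sorts identically
    vals <- sums / cnt
    genes <- rownames(sums)
    message("collapsed ", ndup, " duplicate gene rows by mean")
  }
  rownames(vals) <- genes
  cond <- read_condition_map(condition_map_path)
  expression_matrix(vals, cond)
}

#' Read a sample-condition map (sample ID, tumor/normal)
#' @param path two-column TSV, with or without a header.
#' @return named character vector of conditions.
#' @export
read_condition_map <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("condition map needs two columns: ", path)
  stats::setNames(tolower(as.character(dt[[2]])), as.character(dt[[1]]))
}

#' Write an expression matrix to TSV (full precision round-trip)
#' @param em an `ExpressionMatrix`.
#' @param path output TSV path.
#' @export
write_expression <- function(em, path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  chr <- formatC(em$values, digits = 17, format = "g")
  df <- data.frame(gene = rownames(em$values), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(em$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach gene biotypes to an expression matrix
#' @param em an `ExpressionMatrix`.
#' @param biotypes named character vector (gene symbol -> biotype), e.g.
#'   from [read_gtf_biotypes()] or a two-column table.
#' @return the updated `ExpressionMatrix`; unmatched symbols are logged,
#'   not fatal.
#' @export
set_gene_biotypes <- function(em, biotypes) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  names(biotypes) <- toupper(names(biotypes))
  hit <- intersect(rownames(em$values), names(biotypes))
  miss <- length(biotypes) - length(hit)
  if (miss > 0)
    message(miss, " annotated symbols not present in the expression matrix")
  em$gene_biotype[hit] <- unname(biotypes[hit])
  em
}

#' Extract a gene -> biotype map from a GTF annotation
#'
#' Only `gene` feature rows are consulted. The gene symbol comes from the
#' `gene_name` attribute (falling back to `gene_id`), the biotype from
#' `gene_biotype` (falling back to `gene_type`, the GENCODE spelling).
#' Genes lacking a biotype are omitted with a logged count.
#'
#' @param path GTF/GFF2 file (plain or gzipped).
#' @return named character vector: upper-cased symbol -> biotype.
#' @export
read_gtf_biotypes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (!"type" %in% colnames(mc)) stop("no feature type column in ", path)
  keep <- as.character(mc$type) == "gene"
  if (!any(keep))
    stop("no 'gene' feature records in ", path,
         " (transcript-only annotations are not usable)")
  mc <- mc[keep, , drop = FALSE]
  pick <- function(a, b) {
    x <- if (a %in% colnames(mc)) as.character(mc[[a]]) else
      rep(NA_character_, nrow(mc))
    y <- if (b %in% colnames(mc)) as.character(mc[[b]]) else
      rep(NA_character_, nrow(mc))
    ifelse(is.na(x) | x == "", y, x)
  }
  sym <- pick("gene_name", "gene_id")
  bt <- pick("gene_biotype", "gene_type")
  ok <- !is.na(sym) & sym != "" & !is.na(bt) & bt != ""
  if (sum(!ok) > 0)
    message(sum(!ok), " gene records lacked a symbol or biotype attribute")
  if (!any(ok)) stop("no gene records with usable biotype attributes in ", path)
  res <- stats::setNames(bt[ok], toupper(sym[ok]))
  res[!duplicated(names(res))]
}

#' Read a gene -> biotype two-column table
#' @param path TSV with columns symbol, biotype (header optional).
#' @return named character vector.
#' @export
read_biotype_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("biotype table needs two columns: ", path)
  stats::setNames(as.character(dt[[2]]), toupper(as.character(dt[[1]])))
}

#' Read an immune-related gene list (one symbol per line)
#' @param path plain-text file; blank lines and `#` comments are skipped.
#' @return character vector of unique upper-cased symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  x <- unique(toupper(x))
  if (!length(x)) stop("empty gene list: ", path)
  x
}

#' Read a clinical table
#'
#' Requires columns `sample_id`, `os_time`, `os_event` (matched
#' case-insensitively); `age`, `sex`, `grade`, `stage` are carried when
#' present. Rows with missing survival time or event are dropped and
#' counted (attribute `n_dropped`). Sex is encoded female = 0, male = 1;
#' stage (I-IV) and grade are encoded as ordinal integers.
#'
#' @param path TSV file.
#' @param time_unit recorded unit of `os_time` (`"days"` or `"years"`);
#'   stored as attribute `time_unit` and used when converting ROC horizons.
#' @return a `data.frame` of class `ClinicalTable`.
#' @export
read_clinical <- function(path, time_unit = c("days", "years")) {
  time_unit <- match.arg(time_unit)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  cn <- tolower(colnames(dt))
  need <- c("sample_id", "os_time", "os_event")
  if (!all(need %in% cn))
    stop("clinical table must have columns sample_id, os_time, os_event")
  get <- function(nm) if (nm %in% cn) dt[[which(cn == nm)[1]]] else NULL
  out <- data.frame(sample_id = as.character(get("sample_id")),
                    os_time = suppressWarnings(as.numeric(get("os_time"))),
                    os_event = suppressWarnings(as.numeric(get("os_event"))),
                    stringsAsFactors = FALSE)
  for (nm in c("age", "sex", "grade", "stage")) {
    v <- get(nm)
    if (!is.null(v))
      out[[nm]] <- switch(nm,
                          age = suppressWarnings(as.numeric(v)),
                          sex = encode_sex(v),
                          grade = encode_grade(v),
                          stage = encode_stage(v))
  }
  keep <- !is.na(out$os_time) & !is.na(out$os_event)
  n_dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  if (!nrow(out)) stop("no clinical rows with complete survival data")
  if (n_dropped > 0)
    message("dropped ", n_dropped, " clinical rows with missing survival data")
  if (any(!out$os_event %in% c(0, 1)))
    stop("os_event must be 0 or 1; offending values: ",
         paste(utils::head(setdiff(out$os_event, c(0, 1)), 5), collapse = ", "))
  if (any(out$os_time <= 0))
    stop("os_time must be positive; offending samples: ",
         paste(utils::head(out$sample_id[out$os_time <= 0], 5), collapse = ", "))
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample IDs in clinical table")
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "time_unit") <- time_unit
  class(out) <- c("ClinicalTable", "data.frame")
  out
}

# female = 0, male = 1
encode_sex <- function(x) {
  if (is.numeric(x)) return(ifelse(x %in% c(0, 1), x, NA_real_))
  x <- tolower(trimws(as.character(x)))
  ifelse(x %in% c("female", "f", "0"), 0,
         ifelse(x %in% c("male", "m", "1"), 1, NA_real_))
}

encode_stage <- function(x) {
  if (is.numeric(x)) return(x)
  x <- toupper(trimws(as.character(x)))
  x <- sub("^STAGE[ _]*", "", x)
  roman <- c(I = 1, II = 2, III = 3, IV = 4)
  out <- unname(roman[x])
  num <- suppressWarnings(as.numeric(x))
  ifelse(!is.na(out), out, num)
}

encode_grade <- function(x) {
  if (is.numeric(x)) return(x)
  x <- toupper(trimws(as.character(x)))
  out <- ifelse(x %in% c("LOW", "LOW GRADE", "G1"), 1,
                ifelse(x %in% c("HIGH", "HIGH GRADE", "G3", "G4"), 2,
                       ifelse(x == "G2", 2, NA_real_)))
  num <- suppressWarnings(as.numeric(x))
  ifelse(!is.na(out), out, num)
}

#' Subset an expression matrix by genes and/or samples
#' @param em an `ExpressionMatrix`.
#' @param genes,samples character vectors (default: keep all).
#' @return the subset `ExpressionMatrix`.
#' @export
subset_expression <- function(em, genes = NULL, samples = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(genes)) genes <- rownames(em$values)
  if (is.null(samples)) samples <- colnames(em$values)
  expression_matrix(em$values[genes, samples, drop = FALSE],
                    em$sample_condition[samples],
                    em$gene_biotype)
}

# shared: log2(x + 1) working scale
log2p1 <- function(x) log2(x + 1)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
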