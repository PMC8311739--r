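# Synthetic cohorts with the statistical structure the pair-signature
# analysis assumes: tumor/normal differential expression, immune-gene /
# lncRNA coexpression through shared latent factors, proportional-hazards
# survival driven by planted 0/1 pair indicators, administrative right
# censoring, and clinical covariates coupled to risk.

#' Simulation configuration
#'
#' Defaults emulate the scale of a TCGA bladder-cancer style cohort:
#' 400 tumors, 19 normals, 300 lncRNAs of which 120 are coexpressed with
#' immune genes and 100 of those are differentially expressed, 10 planted
#' prognostic pairs with |beta| in \[0.5, 1\], ~35% censoring.
#'
#' Gene-level parameters (baseline means, tumor shifts, immune partners,
#' planted coefficients) are drawn from `seed`; per-sample noise is drawn
#' from a separate stream so that independent validation cohorts with the
#' same gene parameters can be generated (see `sample_seed` arguments).
#'
#' @param n_tumor,n_normal sample counts.
#' @param n_lnc,n_immune_genes,n_other_genes gene counts by class.
#' @param n_coexpressed_lnc lncRNAs sharing a latent factor with an immune
#'   gene (the planted immune-related set); must be <= `n_lnc`.
#' @param n_de_lnc lncRNAs with a tumor-mean shift (subset of the
#'   coexpressed set, so the planted DEirlncRNA set is recoverable).
#' @param n_planted_pairs number of prognostic pairs planted among DE
#'   lncRNAs (2 distinct genes each).
#' @param beta_range range of |beta_true| for planted pairs; signs are
#'   drawn at random.
#' @param lambda0 baseline hazard (events per time unit, time in years).
#' @param censoring_target target fraction censored (administrative
#'   uniform censoring, tau solved numerically); 0 disables censoring.
#' @param de_log2fc minimum |tumor shift| on the log2 scale; the drawn
#'   shift is `sign * de_log2fc * (1 + Exp(2))`, so `de_log2fc = 0` gives
#'   an exactly null shift.
#' @param rho latent-factor loading; expected Pearson r between a
#'   coexpressed lncRNA and its immune partner is >= rho (the tumor shift
#'   is shared with the partner, so it never attenuates the correlation).
#' @param weibull_shape shape of the Weibull baseline (1 = exponential).
#' @param age_coupling,stage_coupling,grade_coupling strength of the
#'   clinical-covariate coupling to the true linear predictor eta.
#' @param infiltration_coupling,drug_coupling,ici_coupling,assoc_noise_sd
#'   couplings and noise for the downstream association tables.
#' @param seed master seed (gene parameters; sample streams derive from it
#'   unless overridden).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_tumor = 400, n_normal = 19,
                       n_lnc = 300, n_immune_genes = 150, n_other_genes = 500,
                       n_coexpressed_lnc = 120, n_de_lnc = 100,
                       n_planted_pairs = 10, beta_range = c(0.5, 1),
                       lambda0 = 0.08, censoring_target = 0.35,
                       de_log2fc = 1.5, rho = 0.75, weibull_shape = 1,
                       age_coupling = 2, stage_coupling = 0.8,
                       grade_coupling = 0.8,
                       infiltration_coupling = 0.8, drug_coupling = 0.5,
                       ici_coupling = 0.5, assoc_noise_sd = 0.5,
                       seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_de_lnc > cfg$n_coexpressed_lnc)
    stop("n_de_lnc must be <= n_coexpressed_lnc")
  if (cfg$n_coexpressed_lnc > cfg$n_lnc)
    stop("n_coexpressed_lnc must be <= n_lnc")
  if (cfg$n_coexpressed_lnc > cfg$n_immune_genes)
    stop("need n_immune_genes >= n_coexpressed_lnc (one partner each)")
  if (2 * cfg$n_planted_pairs > cfg$n_de_lnc)
    stop("config demands more planted-pair genes than DE lncRNAs")
  if (cfg$censoring_target < 0 || cfg$censoring_target >= 1)
    stop("censoring_target must be in [0, 1)")
  if (cfg$rho < 0 || cfg$rho > 1) stop("rho must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

# Gene-level parameters, a deterministic function of config$seed.
.sim_gene_params <- function(config) {
  set.seed(config$seed)
  lnc <- sprintf("LNC%04d", seq_len(config$n_lnc))
  imm <- sprintf("IMM%04d", seq_len(config$n_immune_genes))
  oth <- sprintf("GEN%04d", seq_len(config$n_other_genes))
  mu_lnc <- stats::runif(config$n_lnc, 2, 6)
  mu_imm <- stats::runif(config$n_immune_genes, 2, 6)
  mu_oth <- stats::runif(config$n_other_genes, 2, 6)
  # partner immune gene per coexpressed lncRNA (injective)
  partner <- seq_len(config$n_coexpressed_lnc)
  # tumor shifts for DE lncRNAs: sign * de_log2fc * (1 + Exp(2))
  sign_de <- ifelse(stats::runif(config$n_de_lnc) < 0.8, 1, -1)
  shift <- sign_de * config$de_log2fc * (1 + stats::rexp(config$n_de_lnc, 2))
  # planted pairs among DE lncRNAs: genes (2k-1, 2k); member B inherits
  # A's mean, shift and immune partner, so S ~ Bernoulli(1/2) i.i.d.
  np <- config$n_planted_pairs
  pairs <- NULL
  if (np > 0) {
    ia <- 2 * seq_len(np) - 1
    ib <- 2 * seq_len(np)
    mu_lnc[ib] <- mu_lnc[ia]
    shift[ib] <- shift[ia]
    partner[ib] <- partner[ia]
    beta <- stats::runif(np, config$beta_range[1], config$beta_range[2]) *
      sample(c(-1, 1), np, replace = TRUE)
    a <- lnc[ia]; b <- lnc[ib]
    flip <- a > b                      # canonical lexicographic orientation
    beta[flip] <- -beta[flip]
    pairs <- data.frame(a = ifelse(flip, b, a), b = ifelse(flip, a, b),
                        beta = beta, stringsAsFactors = FALSE)
    pairs$pair_id <- paste(pairs$a, pairs$b, sep = "|")
  }
  list(lnc = lnc, imm = imm, oth = oth,
       mu_lnc = mu_lnc, mu_imm = mu_imm, mu_oth = mu_oth,
       partner = partner, shift = shift, pairs = pairs)
}

#' Simulate a gene expression matrix with planted structure
#'
#' Log2-scale model: each of the first `n_coexpressed_lnc` lncRNAs shares a
#' standard-normal latent factor with one immune gene (loading `rho`, so
#' the expected Pearson correlation is at least `rho`); each of the first
#' `n_de_lnc` lncRNAs and its immune partner receive a common tumor-mean
#' shift of magnitude >= `de_log2fc`; remaining genes are independent
#' noise. Abundances are `2^x - 1` clipped at zero.
#'
#' @param config a [sim_config()].
#' @param sample_seed seed for the per-sample noise stream (defaults to
#'   `config$seed`); use a different value to draw an independent cohort
#'   with identical gene-level parameters.
#' @return list with elements `expr` (an `ExpressionMatrix`) and `truth`
#'   (ground-truth list: `irlnc`, `de_lnc`, `pairs`, gene parameters, seed).
#' @export
simulate_expression <- function(config, sample_seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  gp <- .sim_gene_params(config)
  set.seed(sample_seed %% .Machine$integer.max)
  n <- config$n_tumor + config$n_normal
  samples <- c(sprintf("TUM%04d", seq_len(config$n_tumor)),
               sprintf("NRM%04d", seq_len(config$n_normal)))
  is_tumor <- c(rep(1, config$n_tumor), rep(0, config$n_normal))
  # latent factors, one per immune gene
  z <- matrix(stats::rnorm(config$n_immune_genes * n),
              config$n_immune_genes, n)
  x_imm <- gp$mu_imm + z
  noise_sd <- sqrt(max(0, 1 - config$rho^2))
  x_lnc <- matrix(stats::rnorm(config$n_lnc * n, sd = 1), config$n_lnc, n)
  ic <- seq_len(config$n_coexpressed_lnc)
  x_lnc[ic, ] <- x_lnc[ic, , drop = FALSE] * noise_sd +
    config$rho * z[gp$partner, , drop = FALSE]
  x_lnc <- gp$mu_lnc + x_lnc
  # tumor shifts (lncRNA and its immune partner share the shift)
  ide <- seq_len(config$n_de_lnc)
  if (config$n_de_lnc > 0) {
    x_lnc[ide, ] <- x_lnc[ide, , drop = FALSE] +
      outer(gp$shift, is_tumor)
    x_imm[gp$partner[ide], ] <- x_imm[gp$partner[ide], , drop = FALSE] +
      outer(gp$shift, is_tumor)
  }
  x_oth <- gp$mu_oth + matrix(stats::rnorm(config$n_other_genes * n),
                              config$n_other_genes, n)
  x <- rbind(x_lnc, x_imm, x_oth)
  rownames(x) <- c(gp$lnc, gp$imm, gp$oth)
  colnames(x) <- samples
  vals <- pmax(2^x - 1, 0)
  bt <- stats::setNames(c(rep("lncRNA", config$n_lnc),
                          rep("protein_coding",
                              config$n_immune_genes + config$n_other_genes)),
                        rownames(x))
  cond <- stats::setNames(ifelse(is_tumor == 1, "tumor", "normal"), samples)
  expr <- expression_matrix(vals, cond, bt)
  truth <- structure(list(irlnc = gp$lnc[ic], de_lnc = gp$lnc[ide],
                          pairs = gp$pairs, immune_genes = gp$imm,
                          gene_params = gp, config = config,
                          seed = config$seed, sample_seed = sample_seed),
                     class = "sim_truth")
  list(expr = expr, truth = truth)
}

# pair indicators for a set of (a, b) pairs from raw abundance
.pair_indicators <- function(values, pairs) {
  S <- (values[pairs$a, , drop = FALSE] >
          values[pairs$b, , drop = FALSE]) + 0L
  rownames(S) <- pairs$pair_id
  S
}

#' Simulate survival and clinical covariates from planted pairs
#'
#' Per tumor sample the linear predictor is `eta = sum(beta_true * S_i)`
#' with `S_i` the 0/1 indicator (expression of A exceeds B). Event times
#' follow a Weibull proportional-hazards model with baseline hazard
#' `lambda0` (exponential when `weibull_shape = 1`); censoring is uniform
#' on (0, tau) with tau solved numerically for the target censoring rate.
#' Age is `Normal(68, 10) + age_coupling * eta`; stage (I-IV) and grade
#' (1-2) are latent-logistic ordinals shifted by eta; sex is independent.
#'
#' @param expr `ExpressionMatrix` from [simulate_expression()].
#' @param truth the matching ground-truth object (updated in place with
#'   `eta` and `true_cutpoint` and returned).
#' @param config the [sim_config()].
#' @param sample_seed RNG seed for this stage (default derives from
#'   `config$seed`).
#' @return list with `clinical` (a `ClinicalTable`, time in years) and the
#'   updated `truth`.
#' @export
simulate_survival <- function(expr, truth, config,
                              sample_seed = config$seed + 1L) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(truth, "sim_truth"))
  set.seed(sample_seed %% .Machine$integer.max)
  tum <- names(expr$sample_condition)[expr$sample_condition == "tumor"]
  n <- length(tum)
  if (is.null(truth$pairs) || !nrow(truth$pairs)) {
    eta <- rep(0, n)
  } else {
    S <- .pair_indicators(expr$values[, tum, drop = FALSE], truth$pairs)
    eta <- drop(crossprod(S, truth$pairs$beta))
  }
  names(eta) <- tum
  u <- stats::rexp(n)                      # unit-exponential deviates
  rate <- config$lambda0 * exp(eta)
  t_true <- if (config$weibull_shape == 1) u / rate else
    (u / rate)^(1 / config$weibull_shape)
  if (config$censoring_target <= 0) {
    os_time <- t_true; os_event <- rep(1L, n)
  } else {
    f <- function(log_tau) {
      tau <- exp(log_tau)
      mean(pmin(t_true, tau) / tau) - config$censoring_target
    }
    lt <- stats::uniroot(f, lower = log(min(t_true) + 1e-12),
                         upper = log(max(t_true) * 50), extendInt = "yes")
    tau <- exp(lt$root)
    cens <- stats::runif(n, 0, tau)
    os_time <- pmin(t_true, cens)
    os_event <- as.integer(t_true <= cens)
  }
  age <- round(stats::rnorm(n, 68, 10) + config$age_coupling * eta)
  sex <- stats::rbinom(n, 1, 0.7)
  lat_stage <- config$stage_coupling * eta + stats::rlogis(n)
  stage <- as.integer(cut(lat_stage,
                          c(-Inf, stats::quantile(lat_stage, c(.25, .55, .85)),
                            Inf), labels = FALSE))
  lat_grade <- config$grade_coupling * eta + stats::rlogis(n)
  grade <- as.integer(lat_grade > stats::quantile(lat_grade, 0.3)) + 1L
  clin <- data.frame(sample_id = tum, os_time = os_time, os_event = os_event,
                     age = age, sex = sex, grade = grade, stage = stage,
                     stringsAsFactors = FALSE)
  attr(clin, "time_unit") <- "years"
  attr(clin, "n_dropped") <- 0L
  class(clin) <- c("ClinicalTable", "data.frame")
  truth$eta <- eta
  truth$true_cutpoint <- stats::median(eta)
  list(clinical = clin, truth = truth)
}

#' Simulate immune-infiltration, ICI-gene and drug-IC50 tables
#'
#' Cell-type fractions are a per-sample softmax of
#' `base + w * eta + noise` with `w > 0` for macrophage/monocyte-like
#' types and `w < 0` for CD4/dendritic-like types (the direction pattern
#' reported for this signature class); fractions are emitted per
#' deconvolution-method tag. Per-drug log-IC50 and per-ICI-gene expression
#' are `base + v * eta + noise` with configurable sign per feature
#' (gefitinib-like positive, cisplatin/docetaxel-like negative,
#' gemcitabine-like null).
#'
#' @param truth ground truth carrying per-sample `eta` (run
#'   [simulate_survival()] first).
#' @param config the [sim_config()]; couplings scale with
#'   `infiltration_coupling`, `drug_coupling`, `ici_coupling`.
#' @param sample_seed RNG seed for this stage.
#' @return list of three long-format `data.frame`s (`infiltration`,
#'   `ic50`, `ici`) with columns feature_id, sample_id, value, source
#'   (plus cell_type/method for infiltration), and the truth direction
#'   tables used to generate them.
#' @export
simulate_associations <- function(truth, config,
                                  sample_seed = config$seed + 2L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(truth$eta))
    stop("per-sample true risk missing; run simulate_survival() first")
  set.seed(sample_seed %% .Machine$integer.max)
  eta <- truth$eta
  n <- length(eta)
  cells <- data.frame(
    cell_type = c("Macrophage", "Monocyte", "Neutrophil", "Fibroblast",
                  "Endothelial cell", "T cell CD4+",
                  "Myeloid dendritic cell activated", "Eosinophil",
                  "B cell", "NK cell"),
    w = c(1, 1, 1, 1, 1, -1, -1, -1, 0, 0) * config$infiltration_coupling,
    stringsAsFactors = FALSE)
  methods <- c("XCELL", "QUANTISEQ", "EPIC")
  base <- stats::runif(nrow(cells), -1, 1)
  infl <- do.call(rbind, lapply(methods, function(m) {
    lin <- base + outer(cells$w, eta) +
      matrix(stats::rnorm(nrow(cells) * n, sd = config$assoc_noise_sd),
             nrow(cells), n)
    frac <- apply(lin, 2, function(v) exp(v) / sum(exp(v)))
    # as.vector() is column-major: cell type varies fastest
    data.frame(feature_id = paste(rep(cells$cell_type, times = n), m,
                                  sep = "_"),
               cell_type = rep(cells$cell_type, times = n),
               sample_id = rep(names(eta), each = nrow(cells)),
               method = m, value = as.vector(frac),
               source = "infiltration", stringsAsFactors = FALSE)
  }))
  drugs <- data.frame(
    drug = c("gefitinib", "cisplatin", "docetaxel", "gemcitabine"),
    v = c(1, -1, -1, 0) * config$drug_coupling, stringsAsFactors = FALSE)
  ic50 <- data.frame(
    feature_id = rep(drugs$drug, each = n),
    sample_id = rep(names(eta), nrow(drugs)),
    value = as.vector(t(2 + outer(drugs$v, eta) +
                          matrix(stats::rnorm(nrow(drugs) * n, sd = 0.8),
                                 nrow(drugs), n))),
    source = "ic50", stringsAsFactors = FALSE)
  ici_genes <- data.frame(
    gene = c("TNFRSF9", "CTLA4", "LAG3", "HAVCR2", "PDCD1"),
    w = c(1, 0, 0, 0, 0) * config$ici_coupling, stringsAsFactors = FALSE)
  ici <- data.frame(
    feature_id = rep(ici_genes$gene, each = n),
    sample_id = rep(names(eta), nrow(ici_genes)),
    value = as.vector(t(4 + outer(ici_genes$w, eta) +
                          matrix(stats::rnorm(nrow(ici_genes) * n, sd = 1),
                                 nrow(ici_genes), n))),
    source = "ici_gene", stringsAsFactors = FALSE)
  list(infiltration = infl, ic50 = ic50, ici = ici,
       cell_truth = cells, drug_truth = drugs, ici_truth = ici_genes)
}

#' Simulate a complete cohort (expression, survival, association tables)
#' @param config a [sim_config()].
#' @param sample_seed base seed for sample-level draws (gene parameters
#'   always come from `config$seed`); stages use `sample_seed`,
#'   `sample_seed + 1`, `sample_seed + 2`.
#' @return list: `expr`, `clinical`, `truth`, `assoc`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            sample_seed = config$seed) {
  se <- simulate_expression(config, sample_seed = sample_seed)
  sv <- simulate_survival(se$expr, se$truth, config,
                          sample_seed = sample_seed + 1L)
  assoc <- simulate_associations(sv$truth, config,
                                 sample_seed = sample_seed + 2L)
  list(expr = se$expr, clinical = sv$clinical, truth = sv$truth,
       assoc = assoc)
}

#' Simulate a cohort with a planted risk-score threshold
#'
#' Continuous scores are uniform on (0, 4); the hazard jumps by a factor
#' `exp(beta)` above the true cut-point. Used to check cut-point recovery.
#'
#' @param n subjects; `c_true` true threshold; `beta` log hazard jump;
#'   `lambda0` baseline hazard; `censoring_target` fraction censored;
#'   `seed` RNG seed.
#' @return data.frame with `score`, `os_time`, `os_event`.
#' @export
simulate_threshold_cohort <- function(n = 400, c_true = 2, beta = 1.5,
                                      lambda0 = 0.15,
                                      censoring_target = 0.3, seed = 1) {
  set.seed(seed %% .Machine$integer.max)
  score <- stats::runif(n, 0, 4)
  rate <- lambda0 * exp(beta * (score > c_true))
  t_true <- stats::rexp(n, rate)
  if (censoring_target <= 0) {
    os_time <- t_true; os_event <- rep(1L, n)
  } else {
    f <- function(log_tau) {
      tau <- exp(log_tau)
      mean(pmin(t_true, tau) / tau) - censoring_target
    }
    tau <- exp(stats::uniroot(f, lower = log(min(t_true) + 1e-12),
                              upper = log(max(t_true) * 50),
                              extendInt = "yes")$root)
    cens <- stats::runif(n, 0, tau)
    os_time <- pmin(t_true, cens)
    os_event <- as.integer(t_true <= cens)
  }
  data.frame(score = score, os_time = os_time, os_event = os_event)
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Emits the same formats the readers consume (`expression.tsv`,
#' `conditions.tsv`, `clinical.tsv`, `immune_genes.txt`, `biotypes.tsv`,
#' association tables) plus a `ground_truth.tsv` sidecar with the planted
#' pairs and a `ground_truth_meta.txt` key-value file.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expr, file.path(dir, "expression.tsv"))
  write_tsv(data.frame(sample_id = names(cohort$expr$sample_condition),
                       condition = unname(cohort$expr$sample_condition)),
            file.path(dir, "conditions.tsv"))
  write_tsv(data.frame(gene = names(cohort$expr$gene_biotype),
                       biotype = unname(cohort$expr$gene_biotype)),
            file.path(dir, "biotypes.tsv"))
  writeLines(cohort$truth$immune_genes, file.path(dir, "immune_genes.txt"))
  write_tsv(as.data.frame(cohort$clinical), file.path(dir, "clinical.tsv"))
  write_tsv(cohort$assoc$infiltration, file.path(dir, "infiltration.tsv"))
  write_tsv(cohort$assoc$ic50, file.path(dir, "ic50.tsv"))
  write_tsv(cohort$assoc$ici, file.path(dir, "ici_expr.tsv"))
  write_tsv(cohort$truth$pairs, file.path(dir, "ground_truth.tsv"))
  meta <- c(paste0("seed=", cohort$truth$seed),
            paste0("sample_seed=", cohort$truth$sample_seed),
            paste0("true_cutpoint=", cohort$truth$true_cutpoint),
            paste0("time_unit=years"))
  writeLines(meta, file.path(dir, "ground_truth_meta.txt"))
  invisible(dir)
}
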