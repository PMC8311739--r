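test_that("simulation is reproducible and respects config validation", {
  cfg <- small_sim_config(seed = 2)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$assoc$ic50, b$assoc$ic50)
  # different sample stream, same gene parameters
  c2 <- simulate_expression(cfg, sample_seed = 999)
  expect_false(identical(a$expr$values, c2$expr$values))
  expect_identical(a$truth$pairs, c2$truth$pairs)
  expect_error(sim_config(n_de_lnc = 50, n_coexpressed_lnc = 20),
               "n_de_lnc")
  expect_error(sim_config(n_planted_pairs = 60, n_de_lnc = 100),
               "planted")
  expect_error(sim_config(censoring_target = 1), "censoring")
})

test_that("rho = 1 with zero noise makes lncRNA and partner collinear", {
  cfg <- sim_config(n_tumor = 15, n_normal = 5, n_lnc = 4,
                    n_immune_genes = 4, n_other_genes = 2,
                    n_coexpressed_lnc = 4, n_de_lnc = 0,
                    n_planted_pairs = 0, rho = 1, seed = 1)
  co <- simulate_expression(cfg)
  lv <- log2(co$expr$values + 1)
  r <- cor(lv["LNC0001", ], lv["IMM0001", ])
  expect_equal(r, 1, tolerance = 1e-12)
})

test_that("planted coexpression passes its own screen on default-style data", {
  cfg <- small_sim_config(seed = 1)
  co <- simulate_expression(cfg)
  scr <- screen_irlncrnas(co$expr, co$truth$immune_genes)
  expect_gte(mean(co$truth$irlnc %in% scr$lncrna[scr$passed]), 0.9)
})

test_that("null DE config produces calls at no more than the nominal rate", {
  calls <- 0L; tested <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_tumor = 100, n_normal = 20, n_lnc = 50,
                      n_immune_genes = 25, n_other_genes = 20,
                      n_coexpressed_lnc = 25, n_de_lnc = 20,
                      n_planted_pairs = 0, de_log2fc = 0, seed = s)
    co <- simulate_expression(cfg)
    de <- de_screen(co$expr, genes = co$truth$irlnc)
    calls <- calls + sum(de$passed)
    tested <- tested + nrow(de)
  }
  expect_lte(calls / tested, 0.05)
})

test_that("survival respects censoring target, null and planted effects", {
  # zero censoring: every subject is an event
  cfg0 <- small_sim_config(seed = 4, censoring_target = 0)
  co0 <- simulate_expression(cfg0)
  sv0 <- simulate_survival(co0$expr, co0$truth, cfg0)
  expect_true(all(sv0$clinical$os_event == 1))
  # default censoring lands near the target
  cfg <- small_sim_config(seed = 4)
  co <- simulate_expression(cfg)
  sv <- simulate_survival(co$expr, co$truth, cfg)
  expect_lt(abs(mean(1 - sv$clinical$os_event) - 0.35), 0.12)
  expect_true(all(sv$clinical$os_time > 0))
  # strong single planted pair: S=1 samples die sooner, several seeds
  for (s in 1:5) {
    cfg1 <- sim_config(n_tumor = 120, n_normal = 10, n_lnc = 20,
                       n_immune_genes = 12, n_other_genes = 5,
                       n_coexpressed_lnc = 10, n_de_lnc = 6,
                       n_planted_pairs = 1, beta_range = c(2, 2),
                       censoring_target = 0, seed = s)
    co1 <- simulate_expression(cfg1)
    # force a positive-effect pair for the direction check
    co1$truth$pairs$beta <- abs(co1$truth$pairs$beta)
    sv1 <- simulate_survival(co1$expr, co1$truth, cfg1)
    s1 <- sv1$truth$eta > 0
    expect_lt(median(sv1$clinical$os_time[s1]),
              median(sv1$clinical$os_time[!s1]))
  }
})

test_that("larger planted effects never lose log-rank power", {
  pow <- vapply(c(0.2, 0.8, 1.6), function(b) {
    hits <- 0L
    for (s in 1:12) {
      cfg <- sim_config(n_tumor = 120, n_normal = 10, n_lnc = 20,
                        n_immune_genes = 12, n_other_genes = 5,
                        n_coexpressed_lnc = 10, n_de_lnc = 6,
                        n_planted_pairs = 1, beta_range = c(b, b),
                        seed = s)
      co <- simulate_expression(cfg)
      sv <- simulate_survival(co$expr, co$truth, cfg)
      g <- factor(sv$truth$eta > median(sv$truth$eta))
      if (nlevels(g) < 2) next
      lr <- logrank_test(sv$clinical$os_time, sv$clinical$os_event, g)
      hits <- hits + (lr$p < 0.05)
    }
    hits
  }, integer(1))
  expect_true(all(diff(pow) >= 0))
})

test_that("association tables carry the planted couplings and directions", {
  cfg <- small_sim_config(seed = 6)
  co <- simulate_cohort(cfg)
  sc <- co$truth$eta
  # near-noiseless positive coupling: Spearman rho ~ 1 for a w>0 cell type
  # zero noise: the fraction is an exactly monotone map of eta, and the
  # tie pattern of eta (a sum over few pairs) is preserved; the coupling
  # stays moderate so the softmax cannot saturate into floating ties
  cfg2 <- small_sim_config(seed = 6, assoc_noise_sd = 0,
                           infiltration_coupling = 2)
  co2 <- simulate_cohort(cfg2)
  infl <- co2$assoc$infiltration
  sub <- infl[infl$feature_id == "Macrophage_XCELL", ]
  rho <- cor(sub$value[match(names(co2$truth$eta), sub$sample_id)],
             co2$truth$eta, method = "spearman")
  expect_equal(rho, 1, tolerance = 1e-9)
  # gefitinib-like drug: higher IC50 in the high-eta half, most seeds
  hits <- 0L
  for (s in 1:10) {
    cs <- small_sim_config(seed = s)
    ch <- simulate_cohort(cs)
    gef <- ch$assoc$ic50[ch$assoc$ic50$feature_id == "gefitinib", ]
    eta <- ch$truth$eta[gef$sample_id]
    hi <- eta > median(eta)
    hits <- hits + (median(gef$value[hi]) > median(gef$value[!hi]))
  }
  expect_gte(hits, 9L)
})

test_that("written cohorts round-trip through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_tumor = 30, n_normal = 8, n_lnc = 12,
                    n_immune_genes = 8, n_other_genes = 4,
                    n_coexpressed_lnc = 8, n_de_lnc = 6,
                    n_planted_pairs = 2, seed = 8)
  co <- simulate_cohort(cfg)
  write_cohort(co, dir)
  em <- read_expression(file.path(dir, "expression.tsv"),
                        file.path(dir, "conditions.tsv"))
  em <- set_gene_biotypes(em, read_biotype_table(file.path(dir,
                                                           "biotypes.tsv")))
  expect_equal(em$values[rownames(co$expr$values), colnames(co$expr$values)],
               co$expr$values, tolerance = 1e-12)
  cl <- read_clinical(file.path(dir, "clinical.tsv"), time_unit = "years")
  expect_equal(nrow(cl), cfg$n_tumor)
  gl <- read_gene_list(file.path(dir, "immune_genes.txt"))
  expect_setequal(gl, co$truth$immune_genes)
  infl <- read_feature_table(file.path(dir, "infiltration.tsv"),
                             "infiltration")
  expect_true(all(c("feature_id", "sample_id", "value") %in%
                    colnames(infl)))
})
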