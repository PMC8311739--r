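# shared small survival fixture with one informative pair among noise
make_selection_fixture <- function(n = 200, n_noise = 30, beta = 1,
                                   seed = 1) {
  set.seed(seed)
  S <- matrix(rbinom((n_noise + 1) * n, 1, 0.5), n_noise + 1, n)
  noise_ids <- if (n_noise > 0)
    paste0("N", sprintf("%03d", seq_len(n_noise)), "A|N",
           sprintf("%03d", seq_len(n_noise)), "B") else character(0)
  rownames(S) <- c("TRUE1|TRUE2", noise_ids)
  colnames(S) <- paste0("P", sprintf("%04d", seq_len(n)))
  tt <- rexp(n, 0.1 * exp(beta * S[1, ]))
  cens <- runif(n, 0, quantile(tt, 0.9) * 2)
  clin <- make_clinical(colnames(S), pmin(tt, cens),
                        as.integer(tt <= cens))
  list(pm = pm_from_S(S), clinical = clin)
}

test_that("univariate screen keeps planted pairs and respects alignment", {
  fx <- make_selection_fixture(n = 300, beta = 1, seed = 3)
  st <- univariate_screen(fx$pm, fx$clinical)
  expect_true("TRUE1|TRUE2" %in% st$kept)
  expect_equal(st$n_in, 31L)
  expect_true(all(st$table$keep == (st$table$p < 0.01), na.rm = TRUE))
  # constant indicator: skipped with a warning, not an NA crash
  S <- fx$pm$S
  S[2, ] <- 1L
  expect_warning(st2 <- univariate_screen(pm_from_S(S), fx$clinical),
                 "constant")
  expect_false(rownames(S)[2] %in% st2$kept)
  # misaligned samples are inner-joined with a log line
  clin_short <- fx$clinical[1:250, ]
  expect_message(univariate_screen(fx$pm, clin_short), "alignment")
})

test_that("univariate screen agrees with the full cox_fit on each pair", {
  fx <- make_selection_fixture(n = 120, n_noise = 5, seed = 5)
  st <- univariate_screen(fx$pm, fx$clinical, p_threshold = 1)
  for (i in seq_len(nrow(st$table))) {
    ref <- cox_fit(fx$clinical$os_time, fx$clinical$os_event,
                   fx$pm$S[st$table$pair_id[i], ])
    expect_equal(st$table$beta[i], ref$coefficients$beta[1],
                 tolerance = 1e-8)
    expect_equal(st$table$p[i], ref$coefficients$p[1], tolerance = 1e-8)
  }
})

test_that("repeated lasso is deterministic and counts frequencies", {
  fx <- make_selection_fixture(n = 150, n_noise = 10, beta = 1.2, seed = 7)
  a <- repeated_lasso(fx$pm, fx$clinical, repetitions = 5, folds = 5,
                      freq_threshold = 1, seed = 42)
  b <- repeated_lasso(fx$pm, fx$clinical, repetitions = 5, folds = 5,
                      freq_threshold = 1, seed = 42)
  expect_identical(a$frequency, b$frequency)
  expect_true(all(a$frequency >= 0 & a$frequency <= 5))
  # single repetition with a strong pair: its frequency is exactly 1
  one <- repeated_lasso(fx$pm, fx$clinical, repetitions = 1, folds = 5,
                        freq_threshold = 0, seed = 9)
  expect_equal(unname(one$frequency["TRUE1|TRUE2"]), 1L)
  expect_true("TRUE1|TRUE2" %in% one$kept)
})

test_that("stepwise drops noise, keeps signal, and never raises the AIC", {
  dropped_noise <- 0L
  for (s in 1:8) {
    fx <- make_selection_fixture(n = 200, n_noise = 1, beta = 1, seed = s)
    m <- stepwise_multivariate(fx$pm, fx$clinical)
    full <- cox_fit(fx$clinical$os_time, fx$clinical$os_event, t(fx$pm$S))
    expect_lte(m$aic, full$aic + 1e-8)
    expect_true("TRUE1|TRUE2" %in% m$pairs)
    dropped_noise <- dropped_noise +
      as.integer(!any(grepl("^N", m$pairs)))
  }
  expect_gte(dropped_noise, 7L)
})

test_that("a single surviving pair yields that pair with its cox AIC", {
  fx <- make_selection_fixture(n = 150, n_noise = 0, beta = 1, seed = 11)
  pm1 <- subset_pairs(fx$pm, pairs = "TRUE1|TRUE2")
  m <- stepwise_multivariate(pm1, fx$clinical)
  expect_identical(m$pairs, "TRUE1|TRUE2")
  ref <- cox_fit(fx$clinical$os_time, fx$clinical$os_event, fx$pm$S[1, ])
  expect_equal(m$aic, ref$aic, tolerance = 1e-8)
  expect_equal(unname(m$beta), ref$coefficients$beta[1], tolerance = 1e-8)
})

test_that("selection stages are nested and permutation destroys selection", {
  fx <- make_selection_fixture(n = 200, n_noise = 20, beta = 1.2, seed = 13)
  st1 <- univariate_screen(fx$pm, fx$clinical, p_threshold = 0.3)
  st2 <- repeated_lasso(subset_pairs(fx$pm, pairs = st1$kept),
                        fx$clinical, repetitions = 10, folds = 5,
                        freq_threshold = 1, seed = 1)
  m <- stepwise_multivariate(subset_pairs(fx$pm, pairs = st2$kept),
                             fx$clinical)
  expect_true(all(st2$kept %in% st1$kept))
  expect_true(all(m$pairs %in% st2$kept))
  # permuting survival times: the univariate screen keeps ~alpha of pairs
  set.seed(99)
  kept <- integer(0)
  for (r in 1:5) {
    perm <- fx$clinical
    idx <- sample(nrow(perm))
    perm$os_time <- perm$os_time[idx]
    perm$os_event <- perm$os_event[idx]
    stp <- tryCatch(univariate_screen(fx$pm, perm, p_threshold = 0.01),
                    error = function(e) list(kept = character(0)))
    kept <- c(kept, length(stp$kept))
  }
  expect_lte(mean(kept), 1.5)
})
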