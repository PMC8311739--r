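test_that("Cox beta matches a grid-search partial-likelihood maximizer", {
  # interleaved covariate: both covariate groups contribute early and late
  # events, so the partial likelihood has an interior maximum
  times <- c(1, 2, 3, 4); events <- c(1, 1, 1, 1); x <- c(0, 1, 1, 0)
  fit <- cox_fit(times, events, x)
  grid <- seq(-5, 5, by = 1e-4)
  # untied data: explicit partial likelihood, scanned over the whole grid
  E <- exp(outer(grid, x))                       # e^(b * x_j), grid x subject
  ll <- rowSums(outer(grid, x[events == 1]))     # sum of eta over event times
  for (i in which(events == 1))
    ll <- ll - log(rowSums(E[, times >= times[i], drop = FALSE]))
  b_or <- grid[which.max(ll)]
  expect_lt(abs(fit$coefficients$beta[1] - b_or), 1e-3)
})

test_that("log partial likelihood on tied data equals the Efron oracle", {
  times <- c(1, 2, 2, 3, 4, 4, 5, 6)
  events <- c(1, 1, 1, 0, 1, 1, 0, 1)
  x <- c(1, 0, 1, 1, 0, 1, 0, 0)
  fit <- cox_fit(times, events, x)
  b <- fit$coefficients$beta[1]
  expect_equal(fit$loglik, efron_loglik(b, times, events, x),
               tolerance = 1e-8)
  # AIC bookkeeping: 2k - 2 logPL
  expect_equal(fit$aic, 2 - 2 * fit$loglik)
})

test_that("cox_fit handles null covariates, flags and invariants", {
  times <- c(1, 2, 3, 4); events <- c(1, 1, 1, 1)
  f0 <- suppressWarnings(cox_fit(times, events,
                                 matrix(0, 4, 1,
                                        dimnames = list(NULL, "z"))))
  expect_equal(f0$coefficients$beta, 0)
  expect_equal(f0$coefficients$hr, 1)
  # affine rescaling of a covariate scales beta inversely
  set.seed(2)
  n <- 60
  x <- rnorm(n)
  tt <- rexp(n, exp(0.7 * x)); ev <- rbinom(n, 1, 0.8)
  f1 <- cox_fit(tt, ev, cbind(a = x))
  f2 <- cox_fit(tt, ev, cbind(a = 10 * x + 3))
  expect_equal(f2$coefficients$beta * 10, f1$coefficients$beta,
               tolerance = 1e-8)
  # martingale residuals sum to ~0 at the MLE
  expect_lt(abs(sum(residuals(f1$fit, type = "martingale"))), 1e-6)
  # HR/CI containment invariant
  expect_true(with(f1$coefficients, ci_low <= hr & hr <= ci_high))
})

test_that("KM estimates match the product-limit oracle", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: survival stays at 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # mixed 8-subject fixture vs hand product-limit
  tt <- c(1, 2, 2, 3, 4, 5, 6, 7)
  ev <- c(1, 1, 0, 1, 0, 1, 0, 1)
  km2 <- km_estimate(tt, ev)
  s <- 1; oracle <- numeric(0); at_risk <- length(tt)
  for (t in sort(unique(tt))) {
    d <- sum(tt == t & ev == 1)
    n <- sum(tt >= t)
    s <- s * (1 - d / n)
    oracle <- c(oracle, s)
  }
  expect_equal(km2$surv, oracle, tolerance = 1e-12)
  expect_true(all(diff(km2$surv) <= 0))
})

test_that("log-rank statistic matches the per-risk-set hand computation", {
  # identical groups: statistic ~0, p ~1
  tt <- c(1, 2, 3, 1, 2, 3); ev <- rep(1, 6); g <- rep(c("a", "b"), each = 3)
  lr0 <- logrank_test(tt, ev, g)
  expect_lt(lr0$statistic, 1e-10)
  expect_gt(lr0$p, 0.999)
  # group A events at (1,2), group B at (3,4)
  tt2 <- c(1, 2, 3, 4); ev2 <- rep(1, 4); g2 <- c("A", "A", "B", "B")
  lr <- logrank_test(tt2, ev2, g2)
  oA <- 0; eA <- 0; v <- 0
  for (t in sort(unique(tt2[ev2 == 1]))) {
    at <- tt2 >= t
    n <- sum(at); nA <- sum(at & g2 == "A"); d <- sum(tt2 == t & ev2 == 1)
    oA <- oA + sum(tt2 == t & ev2 == 1 & g2 == "A")
    eA <- eA + d * nA / n
    if (n > 1) v <- v + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$statistic, (oA - eA)^2 / v, tolerance = 1e-10)
  expect_error(logrank_test(tt2, ev2, rep("A", 4)), "2 groups")
})

test_that("time-dependent ROC matches enumeration when uncensored", {
  # perfect ranking: AUC 1 at any feasible horizon
  tt <- c(1, 2, 3, 4, 5, 6); ev <- rep(1, 6)
  score <- -tt
  expect_equal(td_roc(tt, ev, score, 3.5)$auc, 1)
  # 6-subject fixture vs plain Mann-Whitney enumeration
  score2 <- c(2.5, 0.3, 1.8, 0.9, 2.1, 0.1)
  r <- td_roc(tt, ev, score2, 3.5)
  cases <- score2[tt <= 3.5]; ctrls <- score2[tt > 3.5]
  or <- mean(outer(cases, ctrls, ">") + 0.5 * outer(cases, ctrls, "=="))
  expect_equal(r$auc, or, tolerance = 1e-12)
  expect_equal(r$n_cases, 3); expect_equal(r$n_controls, 3)
  # ROC endpoints
  expect_equal(unlist(r$roc[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$roc[nrow(r$roc), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_error(td_roc(tt, ev, score2, 10), "controls")
})

test_that("td-ROC with score ties counts them half and stays in [0,1]", {
  tt <- c(1, 2, 3, 4); ev <- rep(1, 4)
  score <- c(1, 1, 1, 1)
  expect_equal(td_roc(tt, ev, score, 2.5)$auc, 0.5)
  set.seed(9)
  for (i in 1:5) {
    n <- 80
    t2 <- rexp(n); e2 <- rbinom(n, 1, 0.7); s2 <- rnorm(n)
    a <- td_roc(t2, e2, s2, median(t2))$auc
    expect_gte(a, 0); expect_lte(a, 1)
  }
})

test_that("lasso path is all-zero at lambda_max and unpenalized at 0", {
  set.seed(4)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  tt <- rexp(n, exp(X %*% c(0.8, -0.5, 0))); ev <- rbinom(n, 1, 0.85)
  path <- lasso_cox_path(tt, ev, X)
  expect_true(all(path$beta[, 1] == 0))        # head of the grid
  # warm-started descent down to 0 reproduces the unpenalized fit
  lam <- c(path$lambda, exp(seq(log(min(path$lambda)), log(1e-6),
                                length.out = 20)), 0)
  path0 <- lasso_cox_path(tt, ev, X, lambda = lam)
  ref <- cox_fit(tt, ev, X)$coefficients
  expect_equal(unname(path0$beta[, ncol(path0$beta)]),
               ref$beta[match(c("a", "b", "c"), ref$term)],
               tolerance = 1e-4)
  # a single strong covariate enters the path first
  set.seed(6)
  X2 <- matrix(rnorm(n * 4), n, 4,
               dimnames = list(NULL, paste0("v", 1:4)))
  tt2 <- rexp(n, exp(1.5 * X2[, 2])); ev2 <- rep(1, n)
  p2 <- lasso_cox_path(tt2, ev2, X2)
  first <- apply(p2$beta != 0, 1, function(z) which(z)[1])
  expect_equal(unname(which.min(first)), 2L)
})
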