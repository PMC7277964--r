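test_that("intercept-only Poisson on a constant response has closed form", {
  k <- 3L
  tbl <- data.frame(gap_points = rep(k, 8), f = rnorm(8))
  # a zero-slope covariate: response constant, so the slope estimate is 0
  fit <- fit_poisson_gap(tbl, "f")
  expect_equal(unname(fit$coef[2]), 0, tolerance = 1e-8)
  expect_equal(mean(fit$fitted), k, tolerance = 1e-8)
  expect_equal(fit$log_lik, sum(dpois(rep(k, 8), k, log = TRUE)),
               tolerance = 1e-8)
})

test_that("Poisson fits reach the numerically maximized likelihood", {
  set.seed(51)
  for (r in 1:15) {
    n <- sample(5:12, 1)
    x <- rnorm(n, 60, 8)
    y <- rpois(n, exp(1.2 - 0.02 * (x - 60)))
    if (sum(y) == 0) y[1] <- 1L
    tbl <- data.frame(gap_points = y, f = x)
    fit <- fit_poisson_gap(tbl, "f")
    expect_lt(abs(fit$log_lik - oracle_poisson_loglik(y, x)), 1e-6)
  }
})

test_that("gamma fits reach the numerically maximized likelihood", {
  set.seed(52)
  for (r in 1:15) {
    n <- sample(5:12, 1)
    x <- rnorm(n, 60, 8)
    y <- rgamma(n, shape = 15, scale = exp(4.4 + 0.008 * (x - 60)) / 15)
    tbl <- data.frame(resp = y, f = x)
    fit <- fit_gamma_log(tbl, "f", response = "resp")
    expect_lt(abs(fit$log_lik - oracle_gamma_loglik(y, x)), 1e-5)
  }
})

test_that("a noiseless log-linear gamma response recovers its coefficients", {
  x <- seq(40, 80, length.out = 12)
  a <- 4.2; b <- 0.0075
  y <- exp(a + b * x) * exp(rnorm(12, 0, 1e-6))
  fit <- fit_gamma_log(data.frame(resp = y, f = x), "f", response = "resp")
  expect_equal(unname(fit$coef[1]), a, tolerance = 1e-4)
  expect_equal(unname(fit$coef[2]), b, tolerance = 1e-4)
  expect_equal(unname(fit$exp_coef), exp(b), tolerance = 1e-4)
})

test_that("slope models are at least as likely as intercept-only models", {
  set.seed(53)
  for (r in 1:5) {
    n <- 12
    x <- rnorm(n, 0, 1)
    y <- rpois(n, exp(1 + 0.1 * x)); if (sum(y) == 0) y[1] <- 1L
    tbl <- data.frame(gap_points = y, f = x)
    fit <- fit_poisson_gap(tbl, "f")
    ll0 <- oracle_poisson_loglik(y, rep(0, n))
    expect_gte(fit$log_lik, ll0 - 1e-8)
    yg <- rgamma(n, 10, scale = exp(4 + 0.1 * x) / 10)
    fitg <- fit_gamma_log(data.frame(resp = yg, f = x), "f", response = "resp")
    ll0g <- oracle_gamma_loglik(yg, rep(0, n))
    expect_gte(fitg$log_lik, ll0g - 1e-6)
  }
})

test_that("Poisson response validation rejects non-integers", {
  tbl <- data.frame(gap_points = c(1.5, 2, 3, 4, 5), f = 1:5)
  expect_error(fit_poisson_gap(tbl, "f"), "non-negative integers")
  tbl2 <- data.frame(resp = c(-1, 2, 3, 4, 5), f = 1:5)
  expect_error(fit_gamma_log(tbl2, "f", response = "resp"),
               "strictly positive")
})

test_that("correlation matrices behave on constructed features", {
  set.seed(54)
  n <- 20
  a <- rnorm(n)
  tbl <- data.frame(threshold_hu = rep(0L, n),
                    f1 = a, f2 = a, f3 = -a, f4 = rnorm(n))
  cm <- correlation_matrix(tbl, 0L, features = c("f1", "f2", "f3", "f4"))
  expect_equal(cm$rho["f1", "f2"], 1)
  expect_equal(cm$rho["f1", "f3"], -1)
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 4))

  # invariance under positive affine rescaling, sign flip under negative
  tbl2 <- tbl; tbl2$f4 <- 3 * tbl$f4 + 7
  cm2 <- correlation_matrix(tbl2, 0L, features = c("f1", "f2", "f3", "f4"))
  expect_equal(cm2$rho, cm$rho, tolerance = 1e-12)

  tbl3 <- tbl; tbl3$f5 <- rep(1, n)
  expect_warning(
    cm3 <- correlation_matrix(tbl3, 0L, features = c("f1", "f4", "f5")),
    "zero-variance")
  expect_true(all(is.na(cm3$rho["f5", ])))
})

test_that("HAA is excluded from the correlation matrix at -200 HU", {
  sim <- simulate_gap_cohort(n = 20, seed = 55)
  sim$haa_pct <- 0
  cm <- correlation_matrix(sim, -200L)
  expect_false("haa_pct" %in% cm$labels)
})

test_that("nearly collinear generated features correlate above 0.95", {
  sim <- simulate_gap_cohort(n = 32, seed = 56)
  cm <- correlation_matrix(sim, -200L,
                           features = c("pff_pct", "haa_a_pct", "nl_pct"))
  expect_gte(cm$rho["pff_pct", "haa_a_pct"], 0.95)
})

test_that("log-likelihood ranking orders and flags model pairs", {
  sim <- simulate_gap_cohort(n = 32, seed = 57)
  feats <- c("nl_pct", "pff_pct", "laa_pct", "haa_a_pct", "kurtosis")
  fits <- lapply(feats, function(f) fit_poisson_gap(sim, f, threshold = -200L))
  rk <- rank_by_loglik(fits)
  expect_true(all(diff(rk$table$log_lik) <= 0))

  two <- rank_by_loglik(fits[c(1, 1)])
  expect_equal(two$table$delta_from_best[2], 0)
  expect_false(two$table$distinguishable_from_best[2])

  # a one-point log-likelihood gap separates two models
  f1 <- fits[[1]]; f2 <- fits[[2]]
  f1$log_lik <- -30.76; f2$log_lik <- -31.80
  rk2 <- rank_by_loglik(list(f1, f2))
  expect_equal(rk2$table$delta_from_best[2], 1.04)
  expect_true(rk2$table$distinguishable_from_best[2])

  f2$response <- "other"
  expect_error(rank_by_loglik(list(f1, f2)), "mix responses")
})

test_that("the generating feature recovers its slope across replicates", {
  b <- -0.04
  hits <- 0
  for (r in 1:30) {
    sim <- simulate_gap_cohort(n = 32, b = b, seed = 600 + r)
    fit <- fit_poisson_gap(sim, "nl_pct", threshold = -200L)
    if (abs(fit$coef[2] - b) <= 2 * fit$se[2]) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.85)
})
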