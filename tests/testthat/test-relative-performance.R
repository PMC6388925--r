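test_that("market access is the village mean of market orientation", {
  rec <- data.frame(household_id = c("a", "b", "c"),
                    village_id = c("V1", "V1", "V2"),
                    market_orientation = c(0.2, 0.4, 0.7))
  expect_equal(market_access_proxy(rec), c(0.3, 0.3, 0.7))
  rec$market_orientation <- c(0.5, 0.5, 0.5)
  expect_equal(market_access_proxy(rec), rep(0.5, 3))
  rec$market_orientation <- c(NA, NA, 0.7)
  expect_error(market_access_proxy(rec), "V1")
})

test_that("median regression recovers exact and degenerate fits", {
  x <- 1:10
  expect_warning(fit <- fit_median_regression(2 * x, data.frame(x = x)),
                 "perfect fit")
  expect_equal(suppressWarnings(quantreg_aic(fit)), -Inf)
  expect_equal(unname(fit$coefficients), c(0, 2), tolerance = 1e-8)
  expect_equal(fit$residuals, rep(0, 10), tolerance = 1e-8)

  # intercept-only fit is a sample median (check-loss optimal)
  y <- c(3, 9, 1, 4, 7)
  f0 <- fit_median_regression(y)
  expect_equal(f0$check_loss, sum(0.5 * abs(y - median(y))),
               tolerance = 1e-10)

  Xc <- data.frame(a = 1:8, b = 2 * (1:8))
  expect_error(fit_median_regression(rnorm(8), Xc), "collinear")
})

test_that("fitted coefficients attain the brute-force check-loss minimum", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(7:12, 1)
    p <- sample(1:2, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    y <- rnorm(n, X %*% runif(p, -2, 2))
    fit <- fit_median_regression(y, as.data.frame(X))
    oracle <- oracle_median_fit(y, cbind(1, X))
    expect_equal(fit$check_loss, oracle$check_loss, tolerance = 1e-6)
    expect_equal(unname(fit$coefficients), oracle$coefficients,
                 tolerance = 1e-6)
  }
})

test_that("residual signs satisfy the median property", {
  set.seed(22)
  for (rep in 1:10) {
    n <- 120
    X <- data.frame(x1 = rnorm(n), x2 = runif(n))
    y <- 1 + X$x1 - 2 * X$x2 + rnorm(n)
    fit <- fit_median_regression(y, X)
    pos <- mean(fit$residuals > 0)
    expect_lt(abs(pos - 0.5), 2 / sqrt(n) + fit$k / n)
  }
})

test_that("the quantile-regression AIC follows the stated profile form", {
  rec <- synth_clean(n = 100, seed = 3)$records
  y <- rec$farm_income
  f1 <- fit_median_regression(y, data.frame(x = rec$land_ha))
  expect_equal(f1$aic,
               2 * 2 + 2 * f1$n * log(f1$check_loss / f1$n))
  # identical loss, one extra parameter -> AIC difference exactly 2
  aic_k2 <- 2 * 2 + 2 * 100 * log(0.37)
  aic_k3 <- 2 * 3 + 2 * 100 * log(0.37)
  expect_equal(aic_k3 - aic_k2, 2)
  # halving mean check loss at n = 100 beats one extra parameter
  expect_lt(2 - 200 * log(2), 0)
})

test_that("AIC selection finds planted predictors, shuns pure noise", {
  set.seed(33)
  n <- 500
  signal <- rnorm(n)
  hits_noise <- 0L
  hits_signal <- 0L
  reps <- 25
  for (rep in seq_len(reps)) {
    y <- 3 * signal + rnorm(n)
    cand <- data.frame(signal = signal, noise = rnorm(n))
    fit <- select_model(y, cand)
    hits_signal <- hits_signal + ("signal" %in% fit$covariates)
    hits_noise <- hits_noise + ("noise" %in% fit$covariates)
  }
  expect_equal(hits_signal, reps)
  expect_lt(hits_noise, reps / 2)   # noise selected only in a minority
})

test_that("model selection ties break toward the smaller subset", {
  # mirrored covariates span the same space: subsets {a} and {b} have
  # identical AIC; the joint subset is unfittable and must be skipped;
  # the lexicographically first single covariate wins the tie
  set.seed(4)
  x <- rnorm(30)
  y <- 2 * x + rnorm(30)
  fit <- select_model(y, data.frame(a = x, b = -x))
  tab <- attr(fit, "aic_table")
  expect_equal(tab$aic[tab$subset == "a"], tab$aic[tab$subset == "b"],
               tolerance = 1e-10)
  expect_true(is.na(tab$aic[tab$subset == "a+b"]))
  expect_equal(fit$covariates, "a")
  # empty candidate set falls back to the intercept-only fit
  f0 <- select_model(y, data.frame(row.names = seq_along(y)))
  expect_equal(f0$k, 1L)
})

test_that("residual matrix is shift-equivariant and permutation-equivariant", {
  dat <- synth_clean(n = 80, seed = 12)
  rec <- dat$records
  perf <- performance_matrix(rec)
  rel <- relative_performance(perf, rec)
  expect_equal(nrow(rel$residuals), nrow(rec))
  expect_false(anyNA(rel$residuals))

  # outcome equal to a covariate -> all-zero residuals
  perf0 <- perf
  perf0$scores$cash_income <- rec$land_ha
  rel0 <- suppressWarnings(relative_performance(perf0, rec))
  expect_equal(max(abs(rel0$residuals$cash_income)), 0, tolerance = 1e-8)

  # adding a constant to an outcome leaves residuals unchanged
  perf1 <- perf
  perf1$scores$cash_income <- perf$scores$cash_income + 1000
  rel1 <- relative_performance(perf1, rec)
  expect_equal(rel1$residuals$cash_income, rel$residuals$cash_income,
               tolerance = 1e-6)

  # permuting households permutes residual rows identically
  set.seed(8)
  perm <- sample(nrow(rec))
  perf2 <- perf
  perf2$scores <- perf$scores[perm, ]
  rel2 <- relative_performance(perf2, rec[perm, ])
  expect_equal(rel2$residuals$food_security,
               rel$residuals$food_security[perm], tolerance = 1e-6)
})

test_that("selected models never lose to the intercept-only model", {
  dat <- synth_clean(n = 120, seed = 5)
  perf <- performance_matrix(dat$records)
  rel <- relative_performance(perf, dat$records)
  for (m in rel$models) {
    tab <- attr(m, "aic_table")
    expect_lte(m$aic, tab$aic[tab$subset == "(intercept)"])
  }
})

test_that("planted performance shifts surface in the residuals", {
  dat <- synth_clean(n = 400, seed = 17)
  rec <- dat$records
  perf <- performance_matrix(rec)
  rel <- relative_performance(perf, rec)
  zt <- z_transform(rel$residuals[, -1])
  rc <- cor(dat$truth$quality, rowMeans(zt$scaled), method = "spearman")
  expect_gt(rc, 0.8)
})
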