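test_that("CV curve equals a manual fold-loop refit oracle", {
  set.seed(300)
  n <- 20; p <- 5
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("cg", 1:p)))
  y <- 30 + X %*% c(2, -1, 0.5, 0, 0) + rnorm(n, 0, 0.5)
  y <- as.numeric(y)
  lam <- c(0.5, 0.1, 0.02)
  cv <- cv_lambda(X, y, alpha = 0.5, nfolds = 4, seed = 2, lambda = lam)

  # oracle: explicit per-fold refits at the same lambdas and folds
  oracle <- matrix(NA_real_, 4, length(lam))
  for (f in 1:4) {
    inf <- cv$foldid == f
    fit <- glmnet::glmnet(X[!inf, ], y[!inf], alpha = 0.5, lambda = lam)
    pred <- predict(fit, X[inf, , drop = FALSE], s = lam)
    oracle[f, ] <- colMeans((pred - y[inf])^2)
  }
  expect_equal(cv$cvm, colMeans(oracle), tolerance = 1e-12)
  expect_equal(cv$lambda_min, lam[which.min(colMeans(oracle))])
})

test_that("fold assignment and selected lambda are seed-deterministic", {
  set.seed(4)
  X <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("cg", 1:8)))
  y <- rnorm(40, 35, 3)
  a <- cv_lambda(X, y, nfolds = 5, seed = 9)
  b <- cv_lambda(X, y, nfolds = 5, seed = 9)
  expect_identical(a$foldid, b$foldid)
  expect_identical(a$lambda_min, b$lambda_min)
  expect_error(cv_lambda(X, rep(30, 40), seed = 1), "zero variance")
})

test_that("a noiseless linear signal is fit with near-zero CV error", {
  set.seed(12)
  n <- 200; p <- 30
  X <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("cg", 1:p)))
  y <- as.numeric(28 + X[, 1:3] %*% c(8, -6, 4))
  # deepen the path so the penalty bias vanishes on noiseless data
  lam <- glmnet::glmnet(X, y, alpha = 0.5)$lambda
  lam <- c(lam, min(lam) * 10^(-(1:3)))
  cv <- cv_lambda(X, y, seed = 3, lambda = lam)
  expect_lt(min(cv$cvm), 1e-3)
})

test_that("the trained clock recovers planted CpGs and predicts holdout GA", {
  sim <- simulate_dataset(n_samples = 300, n_probes = 1000, n_causal = 40,
                          noise_sd = 0.2, detection_fail_rate = 0,
                          spot_fraction = 0, seed = 41)
  ga <- sim$truth$true_ga
  idx <- 1:225
  clk <- ga_clock(t(sim$beta[, idx]), unname(ga[idx]), seed = 5)
  expect_s3_class(clk, "ga_clock")
  recall <- mean(names(sim$truth$causal) %in% names(clk$coefficients))
  expect_gte(recall, 0.6)
  pred <- predict(clk, sim$beta[, -idx])
  m <- accuracy_metrics(pred$dnam_ga_weeks, unname(ga[-idx]))
  expect_gte(m$r, 0.9)

  # print/summary/coef surface
  expect_output(print(clk), "Gestational-age epigenetic clock")
  expect_equal(unname(coef(clk)[1]), clk$intercept)
  expect_output(print(summary(clk)), "CpGs")
})

test_that("ridge keeps every probe while the elastic net is sparse", {
  set.seed(6)
  n <- 60; p <- 12
  X <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("cg", 1:p)))
  y <- as.numeric(30 + X[, 1] * 5 + rnorm(n, 0, 0.3))
  ridge <- ga_clock(X, y, alpha = 0, nfolds = 5, seed = 2)
  enet <- ga_clock(X, y, alpha = 0.5, nfolds = 5, seed = 2)
  expect_equal(length(ridge$coefficients), p)
  expect_lt(length(enet$coefficients), p)
})

test_that("prediction is the stated affine form with gold-mean fallback", {
  clk <- structure(list(intercept = 38,
                        coefficients = c(cg1 = -2, cg2 = 1),
                        gold_means = c(cg1 = 0.5, cg2 = 0.25)),
                   class = "ga_clock")
  b <- matrix(c(0.5, 0.1), 2, 1, dimnames = list(c("cg1", "cg2"), "sA"))
  expect_equal(predict(clk, b)$dnam_ga_weeks, 38 - 2 * 0.5 + 1 * 0.1)

  # affine in beta
  b2 <- matrix(c(0.2, 0.9), 2, 1, dimnames = list(c("cg1", "cg2"), "sB"))
  mix <- 0.3 * b + 0.7 * b2
  colnames(mix) <- "sC"
  expect_equal(predict(clk, mix)$dnam_ga_weeks,
               0.3 * predict(clk, b)$dnam_ga_weeks +
               0.7 * predict(clk, b2)$dnam_ga_weeks)

  # one clock CpG missing (50% > 20%) -> error; with a bigger clock, fallback
  expect_error(predict(clk, b[1, , drop = FALSE]), "unreliable")
  clk5 <- structure(list(intercept = 38,
                         coefficients = setNames(rep(1, 6), paste0("cg", 1:6)),
                         gold_means = setNames(rep(0.5, 6), paste0("cg", 1:6))),
                    class = "ga_clock")
  b5 <- matrix(0.4, 5, 1, dimnames = list(paste0("cg", 1:5), "sA"))
  expect_warning(p5 <- predict(clk5, b5), "gold-standard mean")
  expect_equal(p5$dnam_ga_weeks, 38 + 5 * 0.4 + 0.5)
})

test_that("accuracy metrics match the textbook formulas", {
  set.seed(15)
  pred <- runif(50, 25, 44); clin <- runif(50, 25, 44)
  m <- accuracy_metrics(pred, clin)
  e <- abs(pred - clin)
  expect_equal(m$r, sum((pred - mean(pred)) * (clin - mean(clin))) /
                 sqrt(sum((pred - mean(pred))^2) * sum((clin - mean(clin))^2)),
               tolerance = 1e-12)
  expect_equal(m$median_abs_err, median(e), tolerance = 1e-12)
  expect_equal(m$mean_abs_err, mean(e), tolerance = 1e-12)
  expect_equal(m$sd_abs_err, sd(e), tolerance = 1e-12)

  # identity and constant-shift cases
  m1 <- accuracy_metrics(clin, clin)
  expect_equal(m1$r, 1); expect_equal(m1$mean_abs_err, 0)
  m2 <- accuracy_metrics(clin + 1, clin)
  expect_equal(m2$r, 1); expect_equal(m2$median_abs_err, 1)
  expect_error(accuracy_metrics(1:2, 2:3), ">= 3")
})
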