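test_that("EM recovers the weights of a known 3-beta mixture", {
  set.seed(101)
  n <- 10000
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.2, 0.4))
  a <- c(2, 10, 25)[comp]; b <- c(25, 10, 2)[comp]
  x <- rbeta(n, a, b)
  fit <- fit_beta_mixture(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$weights["U"] - 0.4), 0.03)
  expect_lt(abs(fit$weights["H"] - 0.2), 0.03)
  expect_lt(abs(fit$weights["M"] - 0.4), 0.03)
  # component means ordered U < H < M
  mns <- fit$shapes[, 1] / rowSums(fit$shapes)
  expect_true(all(diff(mns) > 0))
  # log-likelihood is non-decreasing across EM iterations
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("a single tight central component is H-dominated", {
  set.seed(5)
  x <- rbeta(5000, 200, 200)   # all values ~0.5
  fit <- fit_beta_mixture(x)
  expect_gt(fit$weights["H"], 0.9)
})

test_that("the fit is invariant to input order", {
  set.seed(9)
  x <- c(rbeta(300, 2, 15), rbeta(200, 8, 8), rbeta(300, 15, 2))
  f1 <- fit_beta_mixture(x)
  f2 <- fit_beta_mixture(sample(x))
  expect_equal(f1$weights, f2$weights, tolerance = 1e-12)
  expect_equal(f1$shapes, f2$shapes, tolerance = 1e-12)
})

test_that("gold standard is the probe-wise mean across pooled samples", {
  m1 <- random_beta(200, 20, seed = 1)
  m2 <- random_beta(200, 10, seed = 2)
  g <- build_gold_standard(list(m1, m2))
  oracle <- sapply(seq_len(200), function(i) mean(c(m1[i, ], m2[i, ])))
  expect_equal(unname(g$values), oracle, tolerance = 1e-14)

  # missing cells ignored in the mean
  m1[1, 1] <- NA
  g2 <- build_gold_standard(list(m1, m2))
  expect_equal(unname(g2$values[1]), mean(c(m1[1, -1], m2[1, ])))

  # a single-sample matrix is its own gold standard
  g3 <- build_gold_standard(list(m1[, 1, drop = FALSE],
                                 m1[, 1, drop = FALSE]))
  expect_equal(g3$values, m1[, 1])

  expect_error(build_gold_standard(list(m1, m2[1:100, ])), "probe mismatch")
})

test_that("calibrating the gold standard against itself is the identity", {
  set.seed(11)
  v <- c(rbeta(400, 2, 12), rbeta(200, 7, 7), rbeta(400, 12, 2))
  names(v) <- sprintf("cg%06d", seq_along(v))
  g <- build_gold_standard(list(matrix(v, dimnames = list(names(v), "s1"))))
  cal <- bmiq_calibrate(g$values, g)
  expect_lt(max(abs(cal - g$values)), 0.01)
})

test_that("calibration moves a shifted sample toward the gold standard", {
  set.seed(13)
  v <- c(rbeta(500, 2, 12), rbeta(300, 7, 7), rbeta(500, 12, 2))
  g_fit_input <- matrix(v, dimnames = list(sprintf("cg%06d", seq_along(v)), "s"))
  g <- build_gold_standard(list(g_fit_input))
  # location-shift on the logit scale
  shifted <- 1 / (1 + exp(-(log(v / (1 - v)) + 0.8)))
  cal <- bmiq_calibrate(shifted, g)
  ks_before <- suppressWarnings(ks.test(shifted, v)$statistic)
  ks_after <- suppressWarnings(ks.test(cal, v)$statistic)
  expect_lt(ks_after, ks_before)
  expect_true(all(cal >= 0 & cal <= 1))
})

test_that("calibration preserves rank order and never creates NAs", {
  set.seed(17)
  v <- sort(c(rbeta(300, 2, 12), rbeta(150, 7, 7), rbeta(300, 12, 2)))
  g_in <- matrix(rev(v), dimnames = list(sprintf("cg%06d", seq_along(v)), "s"))
  g <- build_gold_standard(list(g_in))
  x <- 1 / (1 + exp(-(log(v / (1 - v)) - 0.5)))
  fit <- fit_beta_mixture(x)
  cal <- bmiq_calibrate(x, g, sample_fit = fit)
  st <- gestclock:::classify_states(fit, x)
  for (s in unique(st)) {
    xs <- x[st == s]; cs <- cal[st == s]
    expect_true(all(diff(cs[order(xs)]) >= -1e-12))
  }
  # monotone inputs stay monotone overall
  expect_false(anyNA(cal))

  # NAs pass through untouched, none created
  x2 <- x; x2[c(3, 10)] <- NA
  cal2 <- bmiq_calibrate(x2, g)
  expect_identical(which(is.na(cal2)), which(is.na(x2)))
})
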