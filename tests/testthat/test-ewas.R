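test_that("planted GA slopes are estimated with correct inference", {
  sim <- simulate_dataset(n_samples = 300, n_probes = 800, n_causal = 20,
                          effect_size_range = c(0.02, 0.02), noise_sd = 0.1,
                          cohort_shift_sd = 0, detection_fail_rate = 0,
                          spot_fraction = 0, seed = 70)
  res <- ewas_ga(sim$beta, sim$sheet)
  hit <- res[match(names(sim$truth$causal), res$probe), ]
  expect_true(all(abs(hit$slope - sim$truth$causal) < 0.005))
  expect_true(all(hit$p < 1e-6))

  # per-probe estimates agree with lm() on a few probes
  ga <- effective_ga(sim$sheet)
  ch <- factor(sim$sheet$cohort)
  for (pr in res$probe[c(1, 50, 400)]) {
    fit <- summary(lm(sim$beta[pr, ] ~ ga + ch))$coefficients["ga", ]
    row <- res[res$probe == pr, ]
    expect_equal(row$slope, unname(fit["Estimate"]), tolerance = 1e-10)
    expect_equal(row$se, unname(fit["Std. Error"]), tolerance = 1e-10)
    expect_equal(row$p, unname(fit["Pr(>|t|)"]), tolerance = 1e-10)
  }
})

test_that("slope is invariant to shifting a probe by a constant", {
  sim <- simulate_dataset(n_samples = 80, n_probes = 200, n_causal = 5,
                          detection_fail_rate = 0, spot_fraction = 0,
                          seed = 71)
  b2 <- sim$beta
  b2[1, ] <- pmin(b2[1, ] + 0.1, 1 - 1e-9)
  r1 <- ewas_ga(sim$beta, sim$sheet)
  r2 <- ewas_ga(b2, sim$sheet)
  expect_equal(r1$slope[1], r2$slope[1], tolerance = 1e-9)
})

test_that("a constant probe is flagged degenerate and excluded from counts", {
  sim <- simulate_dataset(n_samples = 50, n_probes = 150, n_causal = 0,
                          detection_fail_rate = 0, spot_fraction = 0,
                          seed = 72)
  b <- sim$beta
  b[3, ] <- 0.5
  res <- ewas_ga(b, sim$sheet)
  expect_true(res$degenerate[3])
  expect_true(is.na(res$p[3]))
  expect_equal(attr(res, "n_significant"),
               sum(res$p < 0.05, na.rm = TRUE))
})

test_that("null p-values are uniform and the 5% count is calibrated", {
  sim <- simulate_dataset(n_samples = 200, n_probes = 2000, n_causal = 0,
                          cohort_shift_sd = 0, dirichlet_conc = 1e6,
                          detection_fail_rate = 0, spot_fraction = 0,
                          seed = 73)
  res <- ewas_ga(sim$beta, sim$sheet)
  frac <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cell adjustment leaves unconfounded statistics nearly unchanged", {
  sim <- simulate_dataset(n_samples = 150, n_probes = 500, n_causal = 25,
                          dirichlet_conc = 1e6,   # no cell variation
                          detection_fail_rate = 0, spot_fraction = 0,
                          seed = 74)
  cells <- sim$truth$cell_proportions +
    matrix(rnorm(length(sim$truth$cell_proportions), 0, 1e-4),
           nrow(sim$truth$cell_proportions))
  r0 <- ewas_ga(sim$beta, sim$sheet)
  r1 <- ewas_ga(sim$beta, sim$sheet, cells = cells, adjust_cells = TRUE)
  cmp <- compare_adjustment(r0, r1)
  expect_gt(cmp$correlation, 0.95)

  # identical inputs give correlation exactly 1
  expect_equal(compare_adjustment(r0, r0)$correlation, 1)

  # independent statistics give correlation near zero
  fake <- r0
  set.seed(1); fake$t <- rnorm(nrow(fake))
  expect_lt(abs(compare_adjustment(r0, fake)$correlation), 0.15)

  # probe mismatch errors
  expect_error(compare_adjustment(r0, r1[-1, ]), "probe sets differ")
})
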