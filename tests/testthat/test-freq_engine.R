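test_that("MME solutions equal brute-force GLS on a small instance", {
  sim <- simulate_trial(toy_params1(n_progeny = 5), seed = 3)
  d <- build_design(sim$table, "T1")
  cs <- covariance_set(4, 1.5, 2, traits = "T1")
  fit <- solve_mme(d, cs)
  or <- gls_oracle(d, 4, 1.5, 2)
  expect_equal(as.numeric(fit$blup_g), or$blup_g, tolerance = 1e-8)
  expect_equal(as.numeric(fit$blup_i), or$blup_i, tolerance = 1e-8)
  expect_equal(unname(fit$blue), or$blue, tolerance = 1e-8)
  expect_equal(fit$logL, gls_reml_loglik(d, 4, 1.5, 2), tolerance = 1e-8)
  expect_equal(reml_loglik(d, cs), fit$logL, tolerance = 1e-12)
})

test_that("BLUPs shrink fully as sigma_g approaches zero and approach progeny
           mean deviations when sigma_g dominates", {
  sim <- simulate_trial(toy_params1(n_progeny = 10, n_blocks = 3), seed = 8)
  d <- build_design(sim$table, "T1")
  tiny <- solve_mme(d, covariance_set(1e-10, 1.5, 2, traits = "T1"))
  expect_lt(max(abs(tiny$blup_g)), 1e-6)
  big <- solve_mme(d, covariance_set(1e6, 1e-8, 1, traits = "T1"))
  df <- as.data.frame(sim$table)
  pm <- tapply(df$T1, df$progeny, mean)
  dev <- pm - mean(pm)
  expect_equal(as.numeric(big$blup_g), as.numeric(dev), tolerance = 1e-3)
})

test_that("zero residual variance is rejected as degenerate", {
  sim <- simulate_trial(toy_params1(n_progeny = 4), seed = 2)
  d <- build_design(sim$table, "T1")
  expect_error(solve_mme(d, covariance_set(1, 1, matrix(0, 1, 1),
                                           traits = "T1")),
               "degenerate")
})

test_that("EM-REML matches the closed-form balanced one-way ANOVA estimates", {
  p <- trial_params(30, 1, 4, "T1", grand_means = 10, sigma_g = 3,
                    sigma_int = matrix(0, 1, 1), sigma_e = 2)
  sim <- simulate_trial(p, seed = 11)
  d <- build_design(sim$table, "T1")
  # crude equal-split start keeps the EM route independent of the oracle
  v0 <- var(sim$table$T1)
  f <- fit_reml(d, init = covariance_set(v0 / 2, NULL, v0 / 2, traits = "T1"),
                include = c(g = TRUE, int = FALSE), tol = 1e-13,
                max_iter = 10000)
  a <- stats::anova(stats::lm(T1 ~ block + progeny,
                              data = as.data.frame(sim$table)))
  ms_g <- a["progeny", "Mean Sq"]; ms_e <- a["Residuals", "Mean Sq"]
  expect_equal(f$components$sigma_g[1, 1], (ms_g - ms_e) / 4, tolerance = 1e-6)
  expect_equal(f$components$sigma_e[1, 1], ms_e, tolerance = 1e-6)
  expect_monotone_trace(f)
  expect_true(f$converged)
})

test_that("EM-REML reaches the balanced MANOVA closed form from a crude start", {
  p <- toy_params3(n_progeny = 120, n_blocks = 3)
  sim <- simulate_trial(p, seed = 5)
  mo <- manova_oracle(sim$table, c("A", "B", "C"))
  expect_true(mo$interior)   # oracle equals REML only at an interior optimum
  d <- build_design(sim$table)
  ymat <- as.matrix(as.data.frame(sim$table)[, c("A", "B", "C")])
  Sp <- cov(ymat)
  f <- fit_reml(d, init = covariance_set(Sp / 3, Sp / 3, Sp / 3,
                                         traits = c("A", "B", "C")),
                tol = 1e-11, max_iter = 5000)
  rel <- function(a, b) max(abs(a - b) / (abs(b) + 1e-6))
  expect_lt(rel(f$components$sigma_g, mo$sigma_g), 1e-5)
  expect_lt(rel(f$components$sigma_int, mo$sigma_int), 1e-5)
  expect_lt(rel(f$components$sigma_e, mo$sigma_e), 1e-5)
  expect_monotone_trace(f)
})

test_that("consistent rescaling shifts the restricted likelihood by the
           Jacobian term only", {
  sim <- simulate_trial(toy_params1(n_progeny = 8), seed = 13)
  d <- build_design(sim$table, "T1")
  cs <- covariance_set(4, 1.5, 2, traits = "T1")
  l1 <- reml_loglik(d, cs)
  c_scale <- 3.7
  d2 <- d
  d2$y <- d$y * c_scale
  cs2 <- covariance_set(4 * c_scale^2, 1.5 * c_scale^2, 2 * c_scale^2,
                        traits = "T1")
  l2 <- reml_loglik(d2, cs2)
  n_p <- length(d$y) - ncol(d$X)
  expect_equal(l2, l1 - n_p * log(c_scale), tolerance = 1e-8)
})

test_that("the REML optimum dominates the generating components", {
  for (s in 1:3) {
    sim <- simulate_trial(toy_params1(n_progeny = 15), seed = 100 + s)
    d <- build_design(sim$table, "T1")
    f <- fit_reml(d, tol = 1e-10)
    at_truth <- reml_loglik(d, covariance_set(4, 1.5, 2, traits = "T1"))
    expect_gte(f$logL + 1e-8, at_truth)
    expect_monotone_trace(f)
  }
})

test_that("a null genetic variance is recovered at the boundary", {
  # Under a true zero component the REML estimate has the boundary null
  # distribution: about half the seeds pin (numerically) at zero, the rest
  # are small positive sampling noise. Both halves are checked.
  ratio <- vapply(1:50, function(s) {
    p <- trial_params(30, 2, 2, "T1", grand_means = 10,
                      sigma_g = matrix(0, 1, 1), sigma_int = 1, sigma_e = 3)
    sim <- simulate_trial(p, seed = 400 + s)
    f <- fit_reml(build_design(sim$table, "T1"), tol = 1e-8, max_iter = 2000)
    phen <- f$components$sigma_g[1, 1] + f$components$sigma_int[1, 1] +
      f$components$sigma_e[1, 1]
    f$components$sigma_g[1, 1] / phen
  }, numeric(1))
  expect_gte(sum(ratio < 1e-3), 18L)   # boundary mass close to one half
  expect_lte(sum(ratio < 1e-3), 35L)
  expect_lt(max(ratio), 0.25)          # positive part is sampling noise
})

test_that("PEV stays within [0, sigma_g2] and deviations sum to zero", {
  sim <- simulate_trial(toy_params3(n_progeny = 25), seed = 19)
  d <- build_design(sim$table)
  f <- fit_reml(d, tol = 1e-8)
  for (k in 1:3) {
    sg2 <- diag(f$components$sigma_g)[k]
    expect_true(all(f$pev_g[, k] >= 0))
    expect_true(all(f$pev_g[, k] <= sg2 + 1e-8))
    expect_lt(abs(sum(f$blup_g[, k])), 1e-5 * sqrt(sg2))
  }
  expect_equal(f$deviance, -2 * f$logL)
})

test_that("AIC and LRT follow their definitions", {
  expect_equal(aic_value(100, 0), 100)
  expect_equal(aic_value(6907.57, 3), 6913.57)
  out <- lrt(7048.74, 6907.57)
  expect_equal(out$lambda, 141.17, tolerance = 1e-10)
  expect_lt(out$p_value, 0.01)
  same <- lrt(50, 50)
  expect_equal(same$lambda, 0)
  expect_equal(same$p_value, 1)
  expect_warning(out2 <- lrt(49.9, 50), "clamped")
  expect_equal(out2$lambda, 0)
})
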