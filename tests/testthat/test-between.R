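test_that("cluster averages strip the estimated household-level effects", {
  prep <- make_prep(20, 3, seed = 43)
  fit <- fit_within(prep)
  avg <- cluster_residual_averages(prep, fit)
  expect_s3_class(avg, "cluster_averages")
  expect_equal(nrow(avg), 20)
  expect_equal(sum(avg$n_c), nrow(prep))
  expect_true(all(avg$n_c_plus == avg$n_c))  # conditional sample: all smokers

  X <- as.matrix(prep[, c("ln_total_expenditure", attr(prep, "controls"))])
  strip1 <- prep$ln_unit_value - drop(X %*% fit$uv$coefficients)
  oracle <- tapply(strip1, prep$cluster_id, mean)
  expect_equal(avg$y1, as.numeric(oracle[avg$cluster_id]), tolerance = 1e-12)
})

test_that("a single-household cluster averages to its own stripped values", {
  prep <- make_prep(12, c(1, 3, 2, 1, 4, 2, 1, 3, 2, 4, 1, 3), seed = 47)
  fit <- fit_within(prep)
  avg <- cluster_residual_averages(prep, fit)
  single <- avg[avg$n_c == 1, ]
  expect_gt(nrow(single), 0)
  X <- as.matrix(prep[, c("ln_total_expenditure", attr(prep, "controls"))])
  for (i in seq_len(nrow(single))) {
    row <- which(prep$cluster_id == single$cluster_id[i])
    expect_length(row, 1)
    expect_equal(single$y1[i],
                 prep$ln_unit_value[row] -
                   sum(X[row, ] * fit$uv$coefficients),
                 tolerance = 1e-12)
  }
})

test_that("with zero estimated slopes y1 is the cluster mean log unit value", {
  # beta = gamma = 0 and no unit-value noise: within variation is exactly zero,
  # so the estimated slopes are zero and nothing is stripped
  p <- true_parameters(beta = 0, sigma_e = 0, sigma_u = 0.012, rho_eu = 0)
  prep <- make_prep(15, 4, params = p, seed = 53)
  fit <- fit_within(prep)
  expect_equal(unname(fit$uv$coefficients), rep(0, 8), tolerance = 1e-10)
  avg <- cluster_residual_averages(prep, fit)
  oracle <- tapply(prep$ln_unit_value, prep$cluster_id, mean)
  expect_equal(avg$y1, as.numeric(oracle[avg$cluster_id]), tolerance = 1e-10)
})

test_that("uncorrected phi equals the OLS slope and the two-pass ratio", {
  prep <- make_prep(40, 5, seed = 59)
  fit <- fit_within(prep)
  avg <- cluster_residual_averages(prep, fit)
  phi <- estimate_phi(avg, 0, 0)
  # oracle 1: direct OLS of y2 on y1
  expect_equal(phi$phi_hat, unname(coef(lm(y2 ~ y1, data = avg))[2]),
               tolerance = 1e-10)
  # oracle 2: independent two-pass covariance / variance computation
  m1 <- mean(avg$y1); m2 <- mean(avg$y2)
  cov2p <- sum((avg$y2 - m2) * (avg$y1 - m1)) / (nrow(avg) - 1)
  var2p <- sum((avg$y1 - m1)^2) / (nrow(avg) - 1)
  expect_equal(phi$phi_hat, cov2p / var2p, tolerance = 1e-10)
})

test_that("exact linear cluster relations are recovered without correction", {
  y1 <- c(-0.4, -0.1, 0.2, 0.5, 0.9)
  avg <- make_averages(y1, 2 * y1)
  expect_equal(estimate_phi(avg)$phi_hat, 2, tolerance = 1e-12)
})

test_that("phi is invariant to constant shifts of y1 or y2", {
  prep <- make_prep(30, 4, seed = 61)
  fit <- fit_within(prep)
  avg <- cluster_residual_averages(prep, fit)
  phi0 <- estimate_phi(avg, fit$sigma11, fit$sigma12)$phi_hat
  avg$y1 <- avg$y1 + 3.7
  expect_equal(estimate_phi(avg, fit$sigma11, fit$sigma12)$phi_hat, phi0,
               tolerance = 1e-12)
  avg$y2 <- avg$y2 - 1.1
  expect_equal(estimate_phi(avg, fit$sigma11, fit$sigma12)$phi_hat, phi0,
               tolerance = 1e-12)
})

test_that("stripped cluster unit values track true prices with slope psi", {
  prep <- make_prep(500, 5, seed = 67)
  truth <- attr(prep, "truth")
  fit <- fit_within(prep)
  avg <- cluster_residual_averages(prep, fit)
  slope <- coef(lm(avg$y1 ~ truth$ln_pi[avg$cluster_id]))[2]
  se <- summary(lm(avg$y1 ~ truth$ln_pi[avg$cluster_id]))$coefficients[2, 2]
  expect_lt(abs(slope - truth$params$psi), 4 * se)
})

test_that("the correction removes attenuation from averaged noise", {
  p <- true_parameters(beta = 0, sigma_e = 0.3, sigma_u = 0.012, rho_eu = 0.3)
  true_phi <- p$theta / p$psi
  est <- sapply(1:40, function(r) {
    prep <- make_prep(200, 5, params = p, seed = 600 + r)
    fit <- fit_within(prep)
    avg <- cluster_residual_averages(prep, fit)
    c(corr = estimate_phi(avg, fit$sigma11, fit$sigma12)$phi_hat,
      unc = estimate_phi(avg, 0, 0)$phi_hat)
  })
  bias_corr <- abs(mean(est["corr", ]) - true_phi)
  bias_unc <- abs(mean(est["unc", ]) - true_phi)
  expect_lt(bias_corr, bias_unc)
})

test_that("degenerate corrections and tiny cluster sets are rejected", {
  avg <- make_averages(c(0.1, 0.2, 0.3, 0.15), c(0.0, 0.1, 0.2, 0.05))
  expect_error(estimate_phi(avg, sigma11 = 100, sigma12 = 0), "degenerate")
  two <- make_averages(c(0.1, 0.2), c(0.0, 0.1))
  expect_error(estimate_phi(two), "3 clusters")
})
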