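test_that("demeaned OLS kernel matches hand-solved normal equations", {
  # 2 clusters x 4 households, 2 regressors: oracle solves the 2x2 system
  y <- c(1.0, 2.0, 1.5, 3.0, 2.5, 4.0, 3.0, 5.0)
  X <- cbind(x1 = c(0.2, 1.1, 0.7, 2.0, 0.5, 1.8, 1.0, 2.6),
             x2 = c(1.0, 0.3, 0.8, 0.1, 1.2, 0.4, 0.9, 0.2))
  cl <- rep(c("a", "b"), each = 4)
  yd <- y - ave(y, cl)
  Xd <- apply(X, 2, function(col) col - ave(col, cl))
  b_oracle <- solve(t(Xd) %*% Xd, t(Xd) %*% yd)
  fit <- deatonuv:::.fe_ols(y, X, cl)
  expect_equal(unname(fit$coefficients), as.numeric(b_oracle), tolerance = 1e-10)
})

test_that("within estimates equal dummy-variable OLS on a small fixture", {
  prep <- make_prep(4, c(9, 8, 7, 6), seed = 13)  # 30 households
  fit <- fit_within(prep)
  X <- as.matrix(prep[, c("ln_total_expenditure", attr(prep, "controls"))])
  for (resp in c("ln_unit_value", "budget_share")) {
    lsdv <- lm(prep[[resp]] ~ X + factor(prep$cluster_id))
    eq <- if (resp == "ln_unit_value") fit$uv else fit$share
    co <- coef(summary(lsdv))
    slope_rows <- paste0("X", colnames(X))
    expect_equal(unname(eq$coefficients), unname(co[slope_rows, "Estimate"]),
                 tolerance = 1e-10)
    expect_equal(unname(eq$se), unname(co[slope_rows, "Std. Error"]),
                 tolerance = 1e-10)
    expect_equal(unname(eq$residuals), unname(residuals(lsdv)),
                 tolerance = 1e-10)
  }
})

test_that("residuals average to zero within every cluster", {
  prep <- make_prep(25, 4, seed = 17)
  fit <- fit_within(prep)
  for (eq in list(fit$uv, fit$share)) {
    cluster_means <- tapply(eq$residuals, prep$cluster_id, mean)
    expect_true(all(abs(cluster_means) < 1e-8))
  }
})

test_that("singleton clusters are inert in slope estimation", {
  prep <- make_prep(20, 4, seed = 23)
  fit0 <- fit_within(prep)
  # append five singleton households as their own clusters
  extra <- make_prep(5, 1, seed = 24)
  extra$cluster_id <- paste0("s", extra$cluster_id)
  combined <- rbind(as.data.frame(prep), as.data.frame(extra))
  class(combined) <- class(prep)
  attr(combined, "controls") <- attr(prep, "controls")
  fit1 <- fit_within(combined)
  expect_equal(fit1$uv$coefficients, fit0$uv$coefficients, tolerance = 1e-10)
  expect_equal(fit1$share$coefficients, fit0$share$coefficients,
               tolerance = 1e-10)
})

test_that("cluster-constant shifts are absorbed by the fixed effects", {
  prep <- make_prep(15, 4, seed = 29)
  fit0 <- fit_within(prep)
  shifted <- prep
  shift <- as.numeric(factor(shifted$cluster_id)) * 0.37
  shifted$ln_unit_value <- shifted$ln_unit_value + shift
  fit1 <- fit_within(shifted)
  expect_equal(fit1$uv$coefficients, fit0$uv$coefficients, tolerance = 1e-8)
})

test_that("no within-cluster variation in the response gives zero slopes", {
  # shares exactly proportional to expenditure: w constant
  prep <- hand_prep(cluster_id = rep(c("a", "b", "c"), each = 5),
                    ln_unit_value = rnorm(15, 7.5, 0.3),
                    budget_share = rep(0.08, 15))
  fit <- fit_within(prep)
  expect_equal(unname(fit$share$coefficients), rep(0, 8), tolerance = 1e-12)
  # and a response constant within clusters but varying between them
  prep2 <- hand_prep(cluster_id = rep(c("a", "b", "c"), each = 5),
                     ln_unit_value = rep(c(7.1, 7.6, 8.0), each = 5),
                     budget_share = runif(15, 0.05, 0.12))
  fit2 <- fit_within(prep2)
  expect_equal(unname(fit2$uv$coefficients), rep(0, 8), tolerance = 1e-10)
})

test_that("collinear designs fail with the offending column named", {
  prep <- make_prep(10, 4, seed = 31)
  prep$prop_males <- prep$prop_adults
  expect_error(fit_within(prep), "prop_males|prop_adults")
})

test_that("residual moments obey their identities and Cauchy-Schwarz", {
  e <- c(1, -1, 2, -2, 0.5)
  expect_equal(residual_moments(e, e, 5, 1, 1)$sigma12,
               residual_moments(e, e, 5, 1, 1)$sigma11)
  u <- c(1, 1, 0, 0, 0)  # orthogonal to e
  expect_equal(sum(e * u), 0)
  expect_equal(residual_moments(e, u, 5, 1, 1)$sigma12, 0)
  expect_error(residual_moments(e, u, 5, 3, 2), "insufficient")

  fit <- fit_within(make_prep(25, 4, seed = 37))
  sigma22 <- sum(fit$share$residuals^2) / fit$share$df
  expect_lte(abs(fit$sigma12), sqrt(fit$sigma11 * sigma22) + 1e-12)
  expect_gte(fit$sigma11, 0)
})

test_that("structural slopes are recovered within 3 SE on generated data", {
  prep <- make_prep(300, 10, seed = 11)
  fit <- fit_within(prep)
  beta_hat <- fit$uv$coefficients[["ln_total_expenditure"]]
  expect_lt(abs(beta_hat - 0.234), 3 * fit$uv$se[["ln_total_expenditure"]])
  eps_hat <- fit$share$coefficients[["ln_total_expenditure"]]
  expect_lt(abs(eps_hat - (-0.056)), 3 * fit$share$se[["ln_total_expenditure"]])
})

test_that("residual moments match the generator's error moments at scale", {
  p <- true_parameters(sigma_e = 0.3, sigma_u = 0.012, rho_eu = 0.3)
  moments <- sapply(1:20, function(r) {
    fit <- fit_within(make_prep(150, 10, params = p, seed = 400 + r))
    c(s11 = fit$sigma11, s12 = fit$sigma12)
  })
  mc_se <- apply(moments, 1, sd) / sqrt(ncol(moments))
  expect_lt(abs(mean(moments["s11", ]) - 0.09), 3 * mc_se["s11"])
  expect_lt(abs(mean(moments["s12", ]) - 0.3 * 0.3 * 0.012), 3 * mc_se["s12"])
})

test_that("cluster fixed-effect joint test is not spuriously significant", {
  # no cluster-level structure in shares: sigma_pi = 0, sigma_fe = 0
  p <- true_parameters(sigma_pi = 0, sigma_fe = 0)
  pvals <- sapply(1:15, function(r) {
    fit_within(make_prep(30, 5, params = p, seed = 500 + r))$share$fe_p
  })
  expect_lte(sum(pvals < 0.05), 3)
  # and with strong cluster structure the test fires
  p2 <- true_parameters(sigma_fe = 0.05)
  fit <- fit_within(make_prep(60, 8, params = p2, seed = 41))
  expect_lt(fit$share$fe_p, 0.01)
})
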