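# Fixed-effects OLS by within-cluster demeaning. Cluster-constant regressors
# (the unobserved cluster log prices) are swept out exactly; slope estimates
# and residuals coincide with dummy-variable least squares.
.fe_ols <- function(y, X, cluster) {
  cl <- factor(cluster)
  n <- length(y)
  k <- ncol(X)
  C <- nlevels(cl)
  counts <- tabulate(cl)
  idx <- as.integer(cl)
  M <- rowsum(cbind(y, X), cl, reorder = TRUE) / counts
  yd <- y - M[idx, 1]
  Xd <- X - M[idx, -1, drop = FALSE]

  fit <- stats::lm.fit(Xd, yd)
  if (fit$rank < k) {
    piv <- fit$qr$pivot
    bad <- colnames(X)[piv[(fit$rank + 1):k]]
    stop("design is rank deficient after within-cluster demeaning; ",
         "collinear column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- n - k - C
  if (df <= 0) {
    stop("insufficient degrees of freedom: n - k - C = ", df, call. = FALSE)
  }
  b <- fit$coefficients
  resid <- fit$residuals
  ssr <- sum(resid^2)
  sigma2 <- ssr / df

  # (X'X)^{-1} on the demeaned design, unpivoted
  R <- qr.R(fit$qr)
  piv <- fit$qr$pivot
  xtx_inv <- chol2inv(R)
  xtx_inv <- xtx_inv[order(piv), order(piv), drop = FALSE]
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- names(b)

  # cluster effects of y - Xb; the grand mean plays the role of the intercept
  ce <- drop(M[, 1] - M[, -1, drop = FALSE] %*% b)
  intercept <- sum(counts * ce) / n
  fe <- ce - intercept
  names(fe) <- levels(cl)

  tss_within <- sum(yd^2)
  r2_within <- if (tss_within > 0) 1 - ssr / tss_within else NA_real_

  # joint significance of the absorbed cluster effects vs pooled OLS
  pooled <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  ssr_pooled <- sum(pooled$residuals^2)
  fe_F <- ((ssr_pooled - ssr) / (C - 1)) / sigma2
  fe_p <- stats::pf(fe_F, C - 1, df, lower.tail = FALSE)

  list(coefficients = b, se = se, intercept = intercept,
       cluster_effects = fe, residuals = resid,
       sigma2 = sigma2, df = df, r2_within = r2_within,
       fe_F = fe_F, fe_p = fe_p, n = n, k = k, n_clusters = C)
}

#' Residual variance and covariance of the two within-cluster equations
#'
#' Degrees of freedom are corrected for the estimated slopes and the absorbed
#' cluster fixed effects: `sigma11 = sum(e^2) / (n - k - C)` and
#' `sigma12 = sum(e u) / (n - k - C)`, where `e` and `u` are the residuals of
#' the unit-value and budget-share equations on the common household sample.
#'
#' @param resid_uv residuals of the unit-value equation.
#' @param resid_share residuals of the budget-share equation, aligned on the
#'   same households.
#' @param n_used number of households in the common sample.
#' @param k_params number of slope parameters per equation.
#' @param n_clusters number of absorbed cluster fixed effects.
#' @return list with `sigma11` and `sigma12`.
#' @export
residual_moments <- function(resid_uv, resid_share, n_used, k_params,
                             n_clusters) {
  stopifnot(length(resid_uv) == length(resid_share),
            length(resid_uv) == n_used)
  df <- n_used - k_params - n_clusters
  if (df <= 0) {
    stop("insufficient data for residual moments: n - k - C = ", df,
         call. = FALSE)
  }
  list(sigma11 = sum(resid_uv^2) / df,
       sigma12 = sum(resid_uv * resid_share) / df)
}

#' Within-cluster stage: unit-value and budget-share regressions
#'
#' Fits, by within-cluster demeaning, the unit-value equation
#' `ln v = lambda + beta ln x + gamma'Z + psi ln pi_c + e` and the budget-share
#' equation `w = alpha + epsilon ln x + delta'Z + theta ln pi_c + FE_c + u`
#' with the cluster-level price terms absorbed (they are cluster-constant, so
#' the within transformation removes them exactly). Both equations use the
#' same household sample, so the residual covariance is well defined.
#' Standard errors are conventional homoskedastic OLS SEs with
#' `n - k - C` degrees of freedom; elasticity inference comes from the
#' cluster bootstrap instead.
#'
#' @param prep a `prepared_survey`.
#' @return an object of class `within_fit` with components `uv` and `share`
#'   (coefficients, SEs, residuals, cluster effects, within R-squared, joint
#'   F test of the fixed effects), residual moments `sigma11`/`sigma12`, and
#'   sample sizes.
#' @export
fit_within <- function(prep) {
  stopifnot(inherits(prep, "prepared_survey"))
  X <- as.matrix(prep[, c("ln_total_expenditure", .control_names)])
  uv <- .fe_ols(prep$ln_unit_value, X, prep$cluster_id)
  share <- .fe_ols(prep$budget_share, X, prep$cluster_id)
  mom <- residual_moments(uv$residuals, share$residuals,
                          n_used = uv$n, k_params = uv$k,
                          n_clusters = uv$n_clusters)
  structure(list(uv = uv, share = share,
                 sigma11 = mom$sigma11, sigma12 = mom$sigma12,
                 n_used = uv$n, n_clusters = uv$n_clusters,
                 k_params = uv$k),
            class = "within_fit")
}

.stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

#' Coefficient table of one within-cluster equation
#'
#' @param fit a `within_fit`.
#' @param equation `"uv"` (log unit value) or `"share"` (budget share).
#' @return data.frame with estimate, SE, t statistic, p value and
#'   significance stars (10/5/1% thresholds).
#' @export
coef_table <- function(fit, equation = c("uv", "share")) {
  stopifnot(inherits(fit, "within_fit"))
  eq <- fit[[match.arg(equation)]]
  t_stat <- eq$coefficients / eq$se
  p <- 2 * stats::pt(abs(t_stat), eq$df, lower.tail = FALSE)
  data.frame(term = names(eq$coefficients),
             estimate = unname(eq$coefficients),
             se = unname(eq$se),
             t = unname(t_stat),
             p = unname(p),
             stars = .stars(unname(p)),
             row.names = NULL)
}

#' @export
print.within_fit <- function(x, digits = 3, ...) {
  cat("Within-cluster fixed-effects regressions (", x$n_used,
      " households, ", x$n_clusters, " clusters)\n", sep = "")
  for (eq in c("uv", "share")) {
    lbl <- if (eq == "uv") "log unit value" else "budget share"
    tab <- coef_table(x, eq)
    tab$estimate <- round(tab$estimate, digits)
    tab$se <- round(tab$se, digits)
    cat("\n", lbl, " equation (within R^2 = ",
        round(x[[eq]]$r2_within, digits), "):\n", sep = "")
    print(tab[, c("term", "estimate", "se", "stars")], row.names = FALSE)
    cat("  constant (grand-mean adjusted): ",
        round(x[[eq]]$intercept, digits), "\n", sep = "")
    cat("  cluster FE joint F = ", round(x[[eq]]$fe_F, digits),
        " (p = ", format.pval(x[[eq]]$fe_p, digits = 3), ")\n", sep = "")
  }
  cat(sprintf("\nresidual moments: sigma11 = %.5g, sigma12 = %.5g\n",
              x$sigma11, x$sigma12))
  invisible(x)
}
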