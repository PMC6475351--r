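#' Cluster averages of stripped unit values and budget shares
#'
#' Removes the estimated household-level effects (expenditure and covariates)
#' from the log unit value and the budget share, then averages within each
#' cluster: `y1_c = mean(ln v - beta_hat ln x - gamma_hat'Z)` and
#' `y2_c = mean(w - epsilon_hat ln x - delta_hat'Z)`. Intercepts are not
#' removed; they are constants absorbed by the centred between-cluster
#' moments. What remains in `y1`/`y2` is the cluster price signal (plus taste
#' effects and averaged noise), which identifies the between-cluster slope.
#'
#' @param prep a `prepared_survey`.
#' @param within a [fit_within()] result.
#' @return data.frame of class `cluster_averages` with columns `cluster_id`,
#'   `y1`, `y2`, `n_c` (households in the cluster) and `n_c_plus` (households
#'   with positive cigarette expenditure; equal to `n_c` in this conditional
#'   pipeline).
#' @export
cluster_residual_averages <- function(prep, within) {
  stopifnot(inherits(prep, "prepared_survey"), inherits(within, "within_fit"))
  X <- as.matrix(prep[, c("ln_total_expenditure", .control_names)])
  strip1 <- prep$ln_unit_value - drop(X %*% within$uv$coefficients)
  strip2 <- prep$budget_share - drop(X %*% within$share$coefficients)
  cl <- factor(prep$cluster_id)
  counts <- tabulate(cl)
  pos <- as.integer(prep$cig_expenditure > 0)
  out <- data.frame(
    cluster_id = levels(cl),
    y1 = drop(rowsum(strip1, cl, reorder = TRUE)) / counts,
    y2 = drop(rowsum(strip2, cl, reorder = TRUE)) / counts,
    n_c = counts,
    n_c_plus = drop(rowsum(pos, cl, reorder = TRUE)),
    row.names = NULL
  )
  class(out) <- c("cluster_averages", "data.frame")
  out
}

#' Measurement-error-corrected between-cluster slope
#'
#' The between-cluster slope of demand on the price proxy,
#' `phi_hat = [Cov(y2, y1) - sigma12 avg(1/n_c)] /
#'            [Var(y1) - sigma11 avg(1/n_c_plus)]`,
#' where the covariance and variance are sample moments across clusters
#' (denominator C - 1) and `avg()` is the arithmetic mean over clusters of
#' the reciprocal household counts. Cluster-average unit values carry averaged
#' household-level measurement error, which attenuates the naive
#' covariance/variance ratio; subtracting the scaled within-stage residual
#' moments removes that bias.
#'
#' @param averages a [cluster_residual_averages()] result.
#' @param sigma11 residual variance of the unit-value equation (0 disables
#'   the correction).
#' @param sigma12 residual covariance of the two equations.
#' @return an object of class `phi_estimate` with the corrected slope
#'   `phi_hat`, the uncorrected ratio `phi_uncorrected`, the raw moments and
#'   correction terms, and the number of clusters used.
#' @export
estimate_phi <- function(averages, sigma11 = 0, sigma12 = 0) {
  stopifnot(inherits(averages, "cluster_averages"))
  C <- nrow(averages)
  if (C < 3) stop("at least 3 clusters are required to estimate phi",
                  call. = FALSE)
  if (any(averages$n_c_plus < 1)) {
    stop("every cluster carrying a unit-value average needs n_c_plus >= 1",
         call. = FALSE)
  }
  cov_y2_y1 <- stats::cov(averages$y2, averages$y1)
  var_y1 <- stats::var(averages$y1)
  correction_num <- sigma12 * mean(1 / averages$n_c)
  correction_den <- sigma11 * mean(1 / averages$n_c_plus)
  den <- var_y1 - correction_den
  if (den <= 1e-10) {
    stop("degenerate measurement-error correction: corrected variance of y1 ",
         "is not positive; more clusters or larger clusters are needed",
         call. = FALSE)
  }
  structure(list(phi_hat = (cov_y2_y1 - correction_num) / den,
                 phi_uncorrected = cov_y2_y1 / var_y1,
                 cov_y2_y1 = cov_y2_y1, var_y1 = var_y1,
                 correction_num = correction_num,
                 correction_den = correction_den,
                 n_clusters_used = C),
            class = "phi_estimate")
}

#' @export
print.phi_estimate <- function(x, digits = 4, ...) {
  cat("Between-cluster slope (", x$n_clusters_used, " clusters)\n", sep = "")
  cat(sprintf("  phi_hat (corrected)   = %.*f\n", digits, x$phi_hat))
  cat(sprintf("  phi     (uncorrected) = %.*f\n", digits, x$phi_uncorrected))
  cat(sprintf("  Cov(y2, y1) = %.3g,  Var(y1) = %.3g\n",
              x$cov_y2_y1, x$var_y1))
  cat(sprintf("  corrections: numerator %.3g, denominator %.3g\n",
              x$correction_num, x$correction_den))
  invisible(x)
}
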