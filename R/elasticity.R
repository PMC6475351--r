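.check_denominator <- function(value, what) {
  if (!is.finite(value) || abs(value) < 1e-10) {
    stop("degenerate parameter combination: ", what,
         " is zero (or numerically indistinguishable from zero)",
         call. = FALSE)
  }
  value
}

#' Quality parameter zeta
#'
#' `zeta = beta / (epsilon + w_bar (1 - beta))`: the expenditure elasticity of
#' quality scaled against the quantity response, used to undo quality shading.
#'
#' @param beta_hat quality-shading elasticity from the unit-value equation.
#' @param epsilon_hat share-expenditure slope from the share equation.
#' @param w_bar sample mean budget share.
#' @return zeta.
#' @export
compute_zeta <- function(beta_hat, epsilon_hat, w_bar) {
  den <- .check_denominator(epsilon_hat + w_bar * (1 - beta_hat),
                            "epsilon + w_bar (1 - beta)")
  beta_hat / den
}

#' Share-price slope theta recovered from the between-cluster slope
#'
#' `theta = phi / (1 + (w_bar - phi) zeta)`.
#'
#' @param phi_hat corrected between-cluster slope.
#' @param zeta_hat quality parameter from [compute_zeta()].
#' @param w_bar sample mean budget share.
#' @return theta.
#' @export
compute_theta <- function(phi_hat, zeta_hat, w_bar) {
  den <- .check_denominator(1 + (w_bar - phi_hat) * zeta_hat,
                            "1 + (w_bar - phi) zeta")
  phi_hat / den
}

#' Unit-value price slope psi
#'
#' `psi = 1 - beta (w_bar - theta) / (epsilon + w_bar)`. Without quality
#' shading (`beta = 0`) unit values move one-for-one with price.
#'
#' @param beta_hat quality-shading elasticity.
#' @param epsilon_hat share-expenditure slope.
#' @param theta_hat share-price slope from [compute_theta()].
#' @param w_bar sample mean budget share.
#' @return psi.
#' @export
compute_psi <- function(beta_hat, epsilon_hat, theta_hat, w_bar) {
  den <- .check_denominator(epsilon_hat + w_bar, "epsilon + w_bar")
  1 - beta_hat * (w_bar - theta_hat) / den
}

#' Conditional price elasticity of demand
#'
#' `price elasticity = theta / w_bar - psi`.
#'
#' @param theta_hat share-price slope.
#' @param psi_hat unit-value price slope.
#' @param w_bar sample mean budget share (> 0).
#' @return the conditional price elasticity.
#' @export
compute_price_elasticity <- function(theta_hat, psi_hat, w_bar) {
  .check_denominator(w_bar, "w_bar")
  theta_hat / w_bar - psi_hat
}

#' Conditional expenditure elasticity of demand
#'
#' `expenditure elasticity = 1 + epsilon / w_bar - beta`.
#'
#' @param epsilon_hat share-expenditure slope.
#' @param beta_hat quality-shading elasticity.
#' @param w_bar sample mean budget share (> 0).
#' @return the conditional expenditure elasticity.
#' @export
compute_expenditure_elasticity <- function(epsilon_hat, beta_hat, w_bar) {
  .check_denominator(w_bar, "w_bar")
  1 + epsilon_hat / w_bar - beta_hat
}

#' Recover price slopes and elasticities from the stage estimates
#'
#' Chains the quality-correction formulas: zeta from `beta`/`epsilon`/`w_bar`,
#' theta from the corrected between-cluster slope `phi`, psi from the
#' quality link, then the conditional price elasticity `theta / w_bar - psi`
#' and expenditure elasticity `1 + epsilon / w_bar - beta`.
#'
#' @param beta_hat within-stage quality-shading elasticity.
#' @param epsilon_hat within-stage share-expenditure slope.
#' @param phi_hat corrected between-cluster slope.
#' @param w_bar sample mean budget share.
#' @return an object of class `elasticity_estimates` with `zeta_hat`,
#'   `theta_hat`, `psi_hat`, `price_elasticity`, `expenditure_elasticity`,
#'   `w_bar` and the inputs.
#' @export
estimate_elasticities <- function(beta_hat, epsilon_hat, phi_hat, w_bar) {
  stopifnot(is.finite(beta_hat), is.finite(epsilon_hat), is.finite(phi_hat),
            is.finite(w_bar), w_bar > 0, w_bar < 1)
  zeta <- compute_zeta(beta_hat, epsilon_hat, w_bar)
  theta <- compute_theta(phi_hat, zeta, w_bar)
  psi <- compute_psi(beta_hat, epsilon_hat, theta, w_bar)
  structure(list(
    w_bar = w_bar,
    zeta_hat = zeta,
    theta_hat = theta,
    psi_hat = psi,
    price_elasticity = compute_price_elasticity(theta, psi, w_bar),
    expenditure_elasticity = compute_expenditure_elasticity(epsilon_hat,
                                                            beta_hat, w_bar),
    beta_hat = beta_hat, epsilon_hat = epsilon_hat, phi_hat = phi_hat
  ), class = "elasticity_estimates")
}

#' @export
print.elasticity_estimates <- function(x, digits = 3, ...) {
  cat("Quality-corrected conditional elasticities\n")
  cat(sprintf("  price elasticity       = %.*f\n", digits, x$price_elasticity))
  cat(sprintf("  expenditure elasticity = %.*f\n", digits,
              x$expenditure_elasticity))
  cat(sprintf("  w_bar = %.4f  zeta = %.4f  theta = %.5f  psi = %.4f\n",
              x$w_bar, x$zeta_hat, x$theta_hat, x$psi_hat))
  invisible(x)
}

#' Full Deaton pipeline on a prepared survey
#'
#' Runs the within-cluster stage, the cluster residual averaging, the
#' measurement-error-corrected between-cluster slope, and the
#' quality-correction formulas, returning the conditional price and
#' expenditure elasticities.
#'
#' @param prep a `prepared_survey`.
#' @param correct apply the measurement-error correction to the
#'   between-cluster slope (default); `FALSE` uses the naive covariance /
#'   variance ratio.
#' @return an object of class `deaton_fit`: list with `within`, `averages`,
#'   `phi`, `w_bar`, `elasticities`, `n_households`, `n_clusters`.
#' @export
deaton_fit <- function(prep, correct = TRUE) {
  stopifnot(inherits(prep, "prepared_survey"))
  within <- fit_within(prep)
  averages <- cluster_residual_averages(prep, within)
  phi <- if (correct) {
    estimate_phi(averages, within$sigma11, within$sigma12)
  } else {
    estimate_phi(averages, 0, 0)
  }
  w_bar <- mean(prep$budget_share)
  el <- estimate_elasticities(within$uv$coefficients[["ln_total_expenditure"]],
                              within$share$coefficients[["ln_total_expenditure"]],
                              phi$phi_hat, w_bar)
  structure(list(within = within, averages = averages, phi = phi,
                 w_bar = w_bar, elasticities = el,
                 n_households = nrow(prep),
                 n_clusters = length(unique(prep$cluster_id)),
                 corrected = correct),
            class = "deaton_fit")
}

#' @export
print.deaton_fit <- function(x, digits = 3, ...) {
  cat("Deaton unit-value fit: ", x$n_households, " households, ",
      x$n_clusters, " clusters",
      if (!x$corrected) " (measurement-error correction OFF)", "\n",
      sep = "")
  cat(sprintf("  beta_hat = %.*f  epsilon_hat = %.*f  phi_hat = %.*f\n",
              digits, x$elasticities$beta_hat,
              digits, x$elasticities$epsilon_hat,
              digits, x$phi$phi_hat))
  print(x$elasticities, digits = digits)
  invisible(x)
}
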