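#' Solve for price slopes consistent with the quality-correction system
#'
#' Given the quality elasticity `beta` (slope of log unit value on log
#' expenditure), the share-expenditure slope `epsilon`, a mean budget share
#' and a target conditional price elasticity, returns the pair
#' `(theta, psi)` — the price slopes of the share and unit-value equations —
#' that the quality-correction formulas recover exactly in the no-noise
#' limit. Used to build generator scenarios whose ground truth the full
#' pipeline can reach.
#'
#' @param beta quality-shading elasticity.
#' @param epsilon share-expenditure slope.
#' @param w_bar mean budget share in (0, 1).
#' @param price_elasticity target conditional price elasticity.
#' @return named numeric vector with elements `theta` and `psi`.
#' @examples
#' solve_price_slopes(0.234, -0.056, 0.0886, -0.326)
#' @export
solve_price_slopes <- function(beta, epsilon, w_bar, price_elasticity) {
  stopifnot(w_bar > 0, w_bar < 1)
  d <- epsilon + w_bar
  if (abs(d) < 1e-10) stop("epsilon + w_bar too close to zero", call. = FALSE)
  # price elasticity = theta / w_bar - psi with psi = 1 - beta (w_bar - theta) / d
  num <- price_elasticity + 1 - beta * w_bar / d
  den <- 1 / w_bar - beta / d
  if (abs(den) < 1e-10) stop("degenerate slope system", call. = FALSE)
  theta <- num / den
  psi <- 1 - beta * (w_bar - theta) / d
  c(theta = theta, psi = psi)
}

#' Ground-truth structural parameters for the survey generator
#'
#' The generator draws, per cluster, a log price `ln pi_c ~ N(0, sigma_pi^2)`
#' and a taste effect `FE_c ~ N(0, sigma_fe^2)`, and per household a log total
#' expenditure `ln x ~ N(mu_lnx, sigma_lnx^2)`, covariates, and correlated
#' measurement errors `(e, u)`. Log unit value and budget share follow the
#' two-equation LA-AIDS structure
#' `ln v = lambda + beta ln x + gamma'Z + psi ln pi_c + e` and
#' `w = alpha + epsilon ln x + delta'Z + theta ln pi_c + FE_c + u`.
#'
#' By default `theta` and `psi` are solved with [solve_price_slopes()] so the
#' generating model is exactly consistent with the quality-correction
#' recovery; when `beta = 0`, `psi` defaults to 1 and
#' `theta = w_bar (price_elasticity + psi)`. The intercepts `alpha` and
#' `lambda` are placed so the implied mean budget share and mean log unit
#' value hit `target_mean_share` and `mean_ln_unit_value` (covariate-mean
#' contributions are evaluated numerically when `gamma`/`delta` are nonzero).
#'
#' Default magnitudes follow the Uganda 2005 cigarette sample: quality
#' elasticity 0.234, share-expenditure slope -0.056, mean share 8.86%, mean
#' unit value ~1952 shillings/pack, mean weekly household expenditure ~34,598
#' shillings, conditional price elasticity -0.326. Dispersion defaults are
#' set so that the implied share distribution stays comfortably inside
#' (0, 1): truncation affects well under 1% of draws and the linear share
#' model is effectively exact.
#'
#' @param beta quality-shading elasticity (ln unit value on ln expenditure).
#' @param epsilon share-expenditure slope.
#' @param price_elasticity target conditional price elasticity used to place
#'   `theta`/`psi` when they are not supplied.
#' @param theta,psi price slopes of the share and unit-value equations;
#'   `NULL` solves them from the other arguments.
#' @param target_mean_share implied mean cigarette budget share in (0, 1).
#' @param mean_ln_unit_value implied mean log unit value.
#' @param mu_lnx,sigma_lnx mean and SD of log household expenditure.
#' @param sigma_pi SD of cluster log prices.
#' @param sigma_fe SD of cluster taste effects.
#' @param sigma_e,sigma_u,rho_eu SDs and correlation of the household-level
#'   errors of the unit-value and share equations (measurement error).
#' @param gamma,delta length-7 covariate coefficient vectors for the
#'   unit-value and share equations (order of [build_controls()]).
#' @return an object of class `true_parameters`.
#' @export
true_parameters <- function(beta = 0.234,
                            epsilon = -0.056,
                            price_elasticity = -0.326,
                            theta = NULL,
                            psi = NULL,
                            target_mean_share = 0.0886,
                            mean_ln_unit_value = log(1952),
                            mu_lnx = log(34598),
                            sigma_lnx = 0.35,
                            sigma_pi = 0.3,
                            sigma_fe = 0.015,
                            sigma_e = 0.3,
                            sigma_u = 0.012,
                            rho_eu = 0.3,
                            gamma = rep(0, 7),
                            delta = rep(0, 7)) {
  stopifnot(length(gamma) == 7, length(delta) == 7,
            sigma_lnx >= 0, sigma_pi >= 0, sigma_fe >= 0,
            sigma_e >= 0, sigma_u >= 0,
            rho_eu >= -1, rho_eu <= 1,
            target_mean_share > 0, target_mean_share < 1)
  if (is.null(theta) || is.null(psi)) {
    if (beta == 0) {
      psi <- if (is.null(psi)) 1 else psi
      theta <- target_mean_share * (price_elasticity + psi)
    } else {
      tp <- solve_price_slopes(beta, epsilon, target_mean_share,
                               price_elasticity)
      theta <- tp[["theta"]]
      psi <- tp[["psi"]]
    }
  }
  ez <- if (any(gamma != 0) || any(delta != 0)) .covariate_means() else rep(0, 7)
  alpha <- target_mean_share - epsilon * mu_lnx - sum(delta * ez)
  lambda <- mean_ln_unit_value - beta * mu_lnx - sum(gamma * ez)
  structure(list(
    beta = beta, epsilon = epsilon, theta = theta, psi = psi,
    alpha = alpha, lambda = lambda,
    sigma_pi = sigma_pi, sigma_fe = sigma_fe,
    sigma_e = sigma_e, sigma_u = sigma_u, rho_eu = rho_eu,
    mu_lnx = mu_lnx, sigma_lnx = sigma_lnx,
    gamma = gamma, delta = delta,
    target_mean_share = target_mean_share
  ), class = "true_parameters")
}

#' @export
print.true_parameters <- function(x, ...) {
  cat("Generator ground truth:\n")
  cat(sprintf("  beta = %.4f  epsilon = %.4f  theta = %.5f  psi = %.4f\n",
              x$beta, x$epsilon, x$theta, x$psi))
  cat(sprintf("  mean share = %.4f  price elasticity = %.4f  expenditure elasticity = %.4f\n",
              x$target_mean_share,
              true_price_elasticity(x, x$target_mean_share),
              true_expenditure_elasticity(x, x$target_mean_share)))
  cat(sprintf("  sigma_pi = %.3f  sigma_fe = %.3f  sigma_e = %.3f  sigma_u = %.3f  rho_eu = %.2f\n",
              x$sigma_pi, x$sigma_fe, x$sigma_e, x$sigma_u, x$rho_eu))
  invisible(x)
}

# Mean of the regression-ready control vector under the generator's covariate
# distributions, evaluated numerically with a private RNG stream.
.covariate_means <- function(n = 2e5) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(171)
  Z <- .draw_controls(n)
  colMeans(Z)
}

# Household covariates loosely calibrated to the Uganda summary table:
# mean household size ~5.6, proportion of adults ~0.55, proportion of males
# ~0.53, schooling of head ~6.5 years, age of head ~41, 87% male heads,
# 89% employed heads.
.draw_covariates <- function(n) {
  data.frame(
    hh_size = 1 + stats::rpois(n, 4.6),
    prop_adults = stats::rbeta(n, 5.5, 4.5),
    prop_males = stats::rbeta(n, 5.3, 4.7),
    educ_years_head = stats::rpois(n, 6.5),
    age_head = 25 + stats::rgamma(n, shape = 4, scale = 4),
    gender_head = ifelse(stats::runif(n) < 0.87, "male", "female"),
    work_head = ifelse(stats::runif(n) < 0.89, "employed", "not_employed"),
    stringsAsFactors = FALSE
  )
}

.draw_controls <- function(n) {
  cov <- .draw_covariates(n)
  cov$household_id <- as.character(seq_len(n))
  build_controls(cov)
}

#' Ground-truth conditional price elasticity of a generator scenario
#'
#' The price elasticity implied by the generating model:
#' `theta / mean_share - psi`.
#'
#' @param params a [true_parameters()] object.
#' @param mean_share mean budget share in (0, 1); defaults to the scenario's
#'   target mean share.
#' @return dimensionless elasticity.
#' @export
true_price_elasticity <- function(params, mean_share = params$target_mean_share) {
  stopifnot(inherits(params, "true_parameters"))
  if (!is.finite(mean_share) || mean_share <= 0 || mean_share >= 1) {
    stop("mean_share must lie strictly inside (0, 1)", call. = FALSE)
  }
  params$theta / mean_share - params$psi
}

#' Ground-truth conditional expenditure elasticity of a generator scenario
#'
#' `1 + epsilon / mean_share - beta`.
#'
#' @inheritParams true_price_elasticity
#' @return dimensionless elasticity.
#' @export
true_expenditure_elasticity <- function(params, mean_share = params$target_mean_share) {
  stopifnot(inherits(params, "true_parameters"))
  if (!is.finite(mean_share) || mean_share <= 0 || mean_share >= 1) {
    stop("mean_share must lie strictly inside (0, 1)", call. = FALSE)
  }
  1 + params$epsilon / mean_share - params$beta
}

#' Simulate a clustered household expenditure survey with known truth
#'
#' Emits smoking households only (matching a conditional-elasticity design):
#' every record has positive cigarette expenditure and quantity. Budget shares
#' are clamped into (0.001, 0.999) with a logged truncation count; scenarios
#' are expected to live in parameter regions where clamping is negligible.
#'
#' @param n_clusters number of clusters (>= 2).
#' @param households_per_cluster households per cluster; scalar or a length-
#'   `n_clusters` vector.
#' @param params a [true_parameters()] scenario.
#' @param seed integer seed; the output is deterministic given the seed.
#' @param year survey wave label written into the records.
#' @param stick_fraction fraction of records whose quantity is expressed in
#'   sticks (unit `"stick"`, quantity multiplied by `pack_size`).
#' @param round_to_stick round quantities to whole sticks (discretization
#'   measurement error); off by default, keeping quantities continuous.
#' @param pack_size cigarettes per pack used for stick conversion.
#' @return a data.frame in the [read_survey()] layout with class
#'   `synthetic_survey`; attribute `truth` holds the drawn cluster log prices
#'   `ln_pi`, taste effects `fe`, the parameter object, and the share
#'   truncation count.
#' @export
simulate_survey <- function(n_clusters,
                            households_per_cluster,
                            params = true_parameters(),
                            seed = NULL,
                            year = 2010,
                            stick_fraction = 0,
                            round_to_stick = FALSE,
                            pack_size = 20) {
  stopifnot(inherits(params, "true_parameters"),
            n_clusters >= 2, all(households_per_cluster >= 0),
            stick_fraction >= 0, stick_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- rep_len(as.integer(households_per_cluster), n_clusters)
  if (sum(m) < 1) stop("at least one household is required", call. = FALSE)

  cluster_ids <- sprintf("c%04d", seq_len(n_clusters))
  ln_pi <- stats::rnorm(n_clusters, 0, params$sigma_pi)
  fe <- stats::rnorm(n_clusters, 0, params$sigma_fe)
  names(ln_pi) <- names(fe) <- cluster_ids

  n <- sum(m)
  ci <- rep(seq_len(n_clusters), times = m)
  lnx <- stats::rnorm(n, params$mu_lnx, params$sigma_lnx)
  cov <- .draw_covariates(n)
  cov$household_id <- sprintf("h%05d", seq_len(n))
  Z <- build_controls(cov)

  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  e <- params$sigma_e * z1
  u <- params$sigma_u * (params$rho_eu * z1 + sqrt(1 - params$rho_eu^2) * z2)

  ln_v <- params$lambda + params$beta * lnx + drop(Z %*% params$gamma) +
    params$psi * ln_pi[ci] + e
  w <- params$alpha + params$epsilon * lnx + drop(Z %*% params$delta) +
    params$theta * ln_pi[ci] + fe[ci] + u

  out_of_range <- w <= 0.001 | w >= 0.999
  n_truncated <- sum(out_of_range)
  if (n_truncated / n > 0.5) {
    stop("more than half of simulated budget shares fall outside (0.001, 0.999); ",
         "the parameter scenario is degenerate", call. = FALSE)
  }
  if (n_truncated / n > 0.1) {
    warning(sprintf("%.1f%% of simulated budget shares truncated into (0.001, 0.999)",
                    100 * n_truncated / n), call. = FALSE)
  } else if (n_truncated > 0) {
    message(n_truncated, " simulated budget share(s) truncated into (0.001, 0.999)")
  }
  w <- pmin(pmax(w, 0.001), 0.999)

  x <- exp(lnx)
  cig_exp <- w * x
  v <- exp(ln_v)
  q_packs <- cig_exp / v

  quantity_unit <- rep("pack", n)
  quantity <- q_packs
  if (stick_fraction > 0) {
    as_sticks <- stats::runif(n) < stick_fraction
    quantity[as_sticks] <- q_packs[as_sticks] * pack_size
    quantity_unit[as_sticks] <- "stick"
  }
  if (round_to_stick) {
    sticks <- ifelse(quantity_unit == "stick", quantity, quantity * pack_size)
    sticks <- pmax(1, round(sticks))
    quantity <- ifelse(quantity_unit == "stick", sticks, sticks / pack_size)
  }

  survey <- data.frame(
    household_id = cov$household_id,
    cluster_id = cluster_ids[ci],
    year = year,
    cig_expenditure = cig_exp,
    cig_quantity = quantity,
    quantity_unit = quantity_unit,
    total_expenditure = x,
    hh_size = cov$hh_size,
    prop_adults = cov$prop_adults,
    prop_males = cov$prop_males,
    educ_years_head = cov$educ_years_head,
    age_head = cov$age_head,
    gender_head = cov$gender_head,
    work_head = cov$work_head,
    stringsAsFactors = FALSE
  )
  structure(survey,
            truth = list(ln_pi = ln_pi, fe = fe, params = params,
                         n_truncated = n_truncated, seed = seed),
            class = c("synthetic_survey", "data.frame"))
}

#' Ground truth attached to a synthetic survey
#'
#' @param survey a [simulate_survey()] result.
#' @return list with `ln_pi`, `fe`, `params`, `n_truncated`, `seed`.
#' @export
survey_truth <- function(survey) {
  truth <- attr(survey, "truth")
  if (is.null(truth)) stop("no ground truth attached: not a synthetic survey",
                           call. = FALSE)
  truth
}
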