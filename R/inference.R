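#' Cluster bootstrap for the elasticity estimates
#'
#' Resamples clusters with replacement (the same number of clusters as
#' observed) and reruns the within, between and elasticity stages on each
#' replicate. Prices vary at the cluster level, so the cluster is the
#' exchangeable resampling unit; resampling households would break the design.
#' Each drawn copy of a cluster is relabelled as a distinct cluster.
#' Standard errors are the SD of the replicate estimates; confidence
#' intervals are 2.5/97.5 percentiles by default (`normal = TRUE` gives
#' normal-approximation intervals instead). Replicates on which a stage fails
#' (e.g. a degenerate measurement-error correction) are dropped and counted;
#' a failure rate above 5% flags the result as unreliable.
#'
#' @param prep a `prepared_survey`.
#' @param B number of bootstrap replicates.
#' @param seed integer seed; mandatory, so results are reproducible.
#' @param statistic function mapping a `prepared_survey` to a named numeric
#'   vector; defaults to the price and expenditure elasticities from
#'   [deaton_fit()].
#' @param correct passed to [deaton_fit()] in the default statistic.
#' @param normal use normal-approximation 95% intervals instead of
#'   percentile intervals.
#' @return an object of class `cluster_bootstrap`: `estimates` (B x p matrix,
#'   failed replicates as NA), `se`, `ci` (2 x p matrix), `n_replicates`,
#'   `n_failed`, `flagged`, `seed`.
#' @export
cluster_bootstrap <- function(prep, B = 1000, seed, statistic = NULL,
                              correct = TRUE, normal = FALSE) {
  stopifnot(inherits(prep, "prepared_survey"), B >= 1)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for the cluster bootstrap", call. = FALSE)
  }
  if (is.null(statistic)) {
    statistic <- function(p) {
      fit <- deaton_fit(p, correct = correct)
      c(price_elasticity = fit$elasticities$price_elasticity,
        expenditure_elasticity = fit$elasticities$expenditure_elasticity)
    }
  }
  # sorted cluster ids make the resampling invariant to record order
  rows_by_cluster <- split(seq_len(nrow(prep)), prep$cluster_id)
  rows_by_cluster <- rows_by_cluster[sort(names(rows_by_cluster))]
  C <- length(rows_by_cluster)

  set.seed(seed)
  point <- statistic(prep)
  p <- length(point)
  est <- matrix(NA_real_, nrow = B, ncol = p,
                dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    draw <- sample.int(C, C, replace = TRUE)
    rows <- rows_by_cluster[draw]
    replicate <- prep[unlist(rows, use.names = FALSE), , drop = FALSE]
    replicate$cluster_id <- rep(sprintf("b%04d", seq_len(C)),
                                times = lengths(rows))
    rownames(replicate) <- NULL
    res <- tryCatch(statistic(replicate), error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else est[b, ] <- res
  }
  if (n_failed == B) {
    stop("all bootstrap replicates failed", call. = FALSE)
  }
  flagged <- n_failed / B > 0.05
  if (flagged) {
    warning(sprintf("%d of %d bootstrap replicates failed (> 5%%); result flagged unreliable",
                    n_failed, B), call. = FALSE)
  }
  se <- apply(est, 2, stats::sd, na.rm = TRUE)
  ci <- if (normal) {
    rbind(point - 1.96 * se, point + 1.96 * se)
  } else {
    apply(est, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  }
  rownames(ci) <- c("2.5%", "97.5%")
  structure(list(point = point, estimates = est, se = se, ci = ci,
                 n_replicates = B, n_failed = n_failed, flagged = flagged,
                 seed = seed, normal = normal),
            class = "cluster_bootstrap")
}

#' @export
print.cluster_bootstrap <- function(x, digits = 3, ...) {
  cat("Cluster bootstrap (B = ", x$n_replicates, ", seed = ", x$seed,
      if (x$n_failed > 0) paste0(", ", x$n_failed, " failed"),
      if (x$flagged) ", FLAGGED unreliable", ")\n", sep = "")
  tab <- data.frame(estimate = round(x$point, digits),
                    se = round(x$se, digits),
                    ci_low = round(x$ci[1, ], digits),
                    ci_high = round(x$ci[2, ], digits))
  print(tab)
  invisible(x)
}

#' SD-based trimming of extreme unit values
#'
#' Robustness protocol for small samples: compute the mean and SD of the raw
#' unit values over the estimation sample (single pass, untrimmed moments)
#' and exclude households whose unit value is equal to or greater than
#' `k` SDs from the mean. Typical choices are `k = 5` and the more stringent
#' `k = 2.5`.
#'
#' @param prep a `prepared_survey`.
#' @param k positive SD multiplier.
#' @return the trimmed `prepared_survey`; attribute `trim_report` records
#'   `k`, the mean and SD used, counts before/after and excluded household
#'   ids.
#' @export
trim_unit_values <- function(prep, k) {
  stopifnot(inherits(prep, "prepared_survey"), is.numeric(k), k > 0)
  v <- prep$unit_value
  m <- mean(v)
  s <- stats::sd(v)
  keep <- if (s == 0) rep(TRUE, length(v)) else abs(v - m) < k * s
  if (!any(keep)) {
    stop("trimming at k = ", k, " SD removed every household", call. = FALSE)
  }
  report <- list(k = k, mean = m, sd = s,
                 n_before = length(v), n_after = sum(keep),
                 n_excluded = sum(!keep),
                 excluded_ids = prep$household_id[!keep])
  out <- prep[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "controls") <- attr(prep, "controls")
  attr(out, "trim_report") <- report
  out
}
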