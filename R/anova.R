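#' One-way ANOVA of unit values on cluster membership
#'
#' Tests the identifying assumption of Deaton's method: that prices, proxied
#' by unit values, vary between clusters. Decomposes the variation of the log
#' unit value (the scale of the downstream unit-value equation; set
#' `log = FALSE` for raw values) into between- and within-cluster sums of
#' squares. The reported R-squared is the share of total variation occurring
#' between clusters.
#'
#' @param prep a `prepared_survey` from [prepare_survey()].
#' @param log analyse log unit values (default) or raw unit values.
#' @return an object of class `uv_anova` with fields `f_statistic`,
#'   `p_value`, `r_squared`, `n_households`, `n_clusters`, `df_between`,
#'   `df_within`.
#' @export
anova_unit_values <- function(prep, log = TRUE) {
  stopifnot(inherits(prep, "prepared_survey"))
  y <- if (log) prep$ln_unit_value else prep$unit_value
  cl <- factor(prep$cluster_id)
  n <- length(y)
  C <- nlevels(cl)
  if (C < 2) stop("at least 2 clusters are required", call. = FALSE)
  if (max(tabulate(cl)) < 2) {
    stop("all clusters are singletons: within-cluster variance is undefined",
         call. = FALSE)
  }
  # anova.lm warns on (near-)perfect fits; the degenerate branches below
  # handle those cases explicitly
  a <- suppressWarnings(stats::anova(stats::lm(y ~ cl)))
  ss_between <- a[["Sum Sq"]][1]
  ss_within <- a[["Sum Sq"]][2]
  ss_total <- ss_between + ss_within
  if (ss_total < 1e-30) {
    f <- 0; p <- 1; r2 <- 0
  } else if (ss_within < 1e-12 * ss_total) {
    f <- Inf; p <- 0; r2 <- 1
  } else {
    f <- a[["F value"]][1]
    p <- a[["Pr(>F)"]][1]
    r2 <- ss_between / ss_total
  }
  structure(list(f_statistic = f, p_value = p, r_squared = r2,
                 n_households = n, n_clusters = C,
                 df_between = C - 1, df_within = n - C,
                 log_scale = log),
            class = "uv_anova")
}

#' @export
print.uv_anova <- function(x, ...) {
  cat("Spatial variation of ", if (x$log_scale) "log " else "",
      "unit values (one-way ANOVA by cluster)\n", sep = "")
  cat(sprintf("  F(%d, %d) = %.3f,  p = %.4f,  between-cluster R^2 = %.3f\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value,
              x$r_squared))
  cat(sprintf("  n = %d households in %d clusters\n",
              x$n_households, x$n_clusters))
  invisible(x)
}
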