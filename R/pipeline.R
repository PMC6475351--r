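#' Read a pipeline configuration file
#'
#' YAML (or JSON, which YAML subsumes) with keys `cpi` (year -> index map),
#' `base_year`, and optional `pack_size` (default 20).
#'
#' @param path path to the configuration file, or a list with the same keys.
#' @return list with elements `cpi` (a [cpi_series()] or `NULL`) and
#'   `pack_size`.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  stopifnot(is.list(cfg))
  cpi <- NULL
  if (!is.null(cfg$cpi)) {
    if (is.null(cfg$base_year)) {
      stop("config supplies a CPI table but no base_year", call. = FALSE)
    }
    cpi <- cpi_series(cfg$cpi, cfg$base_year)
  }
  list(cpi = cpi, pack_size = if (is.null(cfg$pack_size)) 20 else cfg$pack_size)
}

.elasticity_block <- function(fit, boot = NULL) {
  el <- fit$elasticities
  block <- list(
    w_bar = el$w_bar,
    beta_hat = el$beta_hat,
    epsilon_hat = el$epsilon_hat,
    phi_hat = el$phi_hat,
    phi_uncorrected = fit$phi$phi_uncorrected,
    zeta_hat = el$zeta_hat,
    theta_hat = el$theta_hat,
    psi_hat = el$psi_hat,
    price_elasticity = el$price_elasticity,
    expenditure_elasticity = el$expenditure_elasticity,
    n_households = fit$n_households,
    n_clusters = fit$n_clusters
  )
  if (!is.null(boot)) {
    block$bootstrap <- list(
      n_replicates = boot$n_replicates,
      n_failed = boot$n_failed,
      flagged = boot$flagged,
      seed = boot$seed,
      price_elasticity = list(se = unname(boot$se["price_elasticity"]),
                              ci_low = unname(boot$ci[1, "price_elasticity"]),
                              ci_high = unname(boot$ci[2, "price_elasticity"])),
      expenditure_elasticity = list(se = unname(boot$se["expenditure_elasticity"]),
                                    ci_low = unname(boot$ci[1, "expenditure_elasticity"]),
                                    ci_high = unname(boot$ci[2, "expenditure_elasticity"]))
    )
  }
  block
}

.coef_block <- function(fit, eq) {
  tab <- coef_table(fit, eq)
  list(coefficients = tab,
       intercept = fit[[eq]]$intercept,
       r2_within = fit[[eq]]$r2_within,
       fe_joint_F = fit[[eq]]$fe_F,
       fe_joint_p = fit[[eq]]$fe_p,
       n = fit[[eq]]$n)
}

#' Run the full unit-value elasticity pipeline
#'
#' Preprocess, summarize, test spatial price variation, fit the within and
#' between stages, recover the elasticities, bootstrap their SEs, and
#' optionally rerun under SD-based unit-value trimming. When `out_dir` is
#' given, writes `results.json` (full precision, machine readable),
#' `summary.csv`, `cluster_averages.csv` and `tables.txt` (display tables
#' rounded to 3 decimals with 10/5/1% significance stars). Reruns with an
#' identical configuration produce byte-identical outputs.
#'
#' @param input path to a survey CSV or a data.frame in the [read_survey()]
#'   layout.
#' @param config optional path to a YAML config (or list) with `cpi`,
#'   `base_year`, `pack_size`; see [read_config()].
#' @param trim_k numeric vector of SD multipliers for robustness reruns
#'   (e.g. `c(5, 2.5)`); empty for none.
#' @param bootstrap_B bootstrap replicates (0 disables the bootstrap).
#' @param seed integer seed for the bootstrap.
#' @param out_dir optional output directory (created if needed).
#' @return invisibly, a list with `prep`, `summary`, `anova`, `fit`,
#'   `bootstrap`, `robustness` and the machine-readable `results` list.
#' @export
run_pipeline <- function(input, config = NULL, trim_k = numeric(0),
                         bootstrap_B = 1000, seed = 1, out_dir = NULL) {
  survey <- if (is.character(input)) read_survey(input) else input
  cfg <- if (is.null(config)) list(cpi = NULL, pack_size = 20) else read_config(config)

  prep <- prepare_survey(survey, cpi = cfg$cpi, pack_size = cfg$pack_size)
  summary <- summarize_survey(prep)
  anova <- anova_unit_values(prep)
  fit <- deaton_fit(prep)
  boot <- if (bootstrap_B > 0) {
    cluster_bootstrap(prep, B = bootstrap_B, seed = seed)
  } else NULL

  robustness <- list()
  for (k in trim_k) {
    trimmed <- trim_unit_values(prep, k)
    tfit <- deaton_fit(trimmed)
    tboot <- if (bootstrap_B > 0) {
      cluster_bootstrap(trimmed, B = bootstrap_B, seed = seed)
    } else NULL
    robustness[[paste0("trim_", format(k))]] <- list(
      k = k,
      n_excluded = attr(trimmed, "trim_report")$n_excluded,
      fit = tfit, bootstrap = tboot
    )
  }

  results <- list(
    run = list(seed = seed, bootstrap_B = bootstrap_B,
               trim_k = as.numeric(trim_k),
               pack_size = cfg$pack_size,
               exclusions = as.list(attr(prep, "exclusions"))),
    summary = as.list(as.data.frame(summary)),
    anova = list(f_statistic = anova$f_statistic, p_value = anova$p_value,
                 r_squared = anova$r_squared,
                 n_households = anova$n_households,
                 n_clusters = anova$n_clusters),
    within = list(unit_value = .coef_block(fit$within, "uv"),
                  budget_share = .coef_block(fit$within, "share"),
                  sigma11 = fit$within$sigma11,
                  sigma12 = fit$within$sigma12),
    between = list(phi_hat = fit$phi$phi_hat,
                   phi_uncorrected = fit$phi$phi_uncorrected,
                   cov_y2_y1 = fit$phi$cov_y2_y1,
                   var_y1 = fit$phi$var_y1,
                   correction_num = fit$phi$correction_num,
                   correction_den = fit$phi$correction_den,
                   n_clusters_used = fit$phi$n_clusters_used),
    elasticities = .elasticity_block(fit, boot),
    robustness = lapply(robustness, function(r) {
      c(list(k = r$k, n_excluded = r$n_excluded),
        .elasticity_block(r$fit, r$bootstrap))
    })
  )
  validate_results(results)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
    utils::write.csv(as.data.frame(summary),
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(fit$averages),
                     file.path(out_dir, "cluster_averages.csv"),
                     row.names = FALSE)
    writeLines(.format_report(summary, anova, fit, boot, robustness),
               file.path(out_dir, "tables.txt"))
  }

  invisible(list(prep = prep, summary = summary, anova = anova, fit = fit,
                 bootstrap = boot, robustness = robustness,
                 results = results))
}

.fmt <- function(x, digits = 3) formatC(x, digits = digits, format = "f")

.format_report <- function(summary, anova, fit, boot, robustness) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, paste0(...))
  add("== Summary statistics ==")
  df <- as.data.frame(summary)
  for (nm in names(df)) add(sprintf("  %-26s %s", nm, .fmt(df[[nm]], 2)))
  add("")
  add("== Spatial variation of log unit values (one-way ANOVA) ==")
  add(sprintf("  F(%d, %d) = %s, p = %s, between-cluster R^2 = %s, n = %d",
              anova$df_between, anova$df_within, .fmt(anova$f_statistic),
              .fmt(anova$p_value), .fmt(anova$r_squared), anova$n_households))
  add("")
  for (eq in c("uv", "share")) {
    add("== ", if (eq == "uv") "Unit-value" else "Budget-share",
        " equation (within-cluster fixed effects) ==")
    tab <- coef_table(fit$within, eq)
    for (i in seq_len(nrow(tab))) {
      add(sprintf("  %-22s %8s%-3s (%s)", tab$term[i],
                  .fmt(tab$estimate[i]), tab$stars[i], .fmt(tab$se[i])))
    }
    add(sprintf("  constant %s, within R^2 %s, FE joint F %s (p %s), n %d",
                .fmt(fit$within[[eq]]$intercept),
                .fmt(fit$within[[eq]]$r2_within),
                .fmt(fit$within[[eq]]$fe_F),
                .fmt(fit$within[[eq]]$fe_p), fit$within[[eq]]$n))
    add("")
  }
  add("== Elasticities ==")
  add(.format_elasticity_line(fit, boot))
  if (length(robustness) > 0) {
    add("")
    add("== Robustness: SD-trimmed unit values ==")
    for (r in robustness) {
      add(sprintf("  k = %s SD (%d excluded):", format(r$k), r$n_excluded))
      add("  ", .format_elasticity_line(r$fit, r$bootstrap))
    }
  }
  lines
}

.format_elasticity_line <- function(fit, boot) {
  el <- fit$elasticities
  line <- sprintf("  price elasticity %s, expenditure elasticity %s (n = %d, clusters = %d)",
                  .fmt(el$price_elasticity), .fmt(el$expenditure_elasticity),
                  fit$n_households, fit$n_clusters)
  if (!is.null(boot)) {
    line <- paste0(line, sprintf(
      "\n    bootstrap: price SE %s, 95%% CI (%s, %s); expenditure SE %s, 95%% CI (%s, %s)",
      .fmt(boot$se["price_elasticity"]),
      .fmt(boot$ci[1, "price_elasticity"]),
      .fmt(boot$ci[2, "price_elasticity"]),
      .fmt(boot$se["expenditure_elasticity"]),
      .fmt(boot$ci[1, "expenditure_elasticity"]),
      .fmt(boot$ci[2, "expenditure_elasticity"])))
  }
  line
}

#' Validate a pipeline results list against the shipped schema
#'
#' Structural validation against `inst/schema/results-schema.json`: required
#' keys must be present and leaf values must have the declared JSON type.
#'
#' @param results the machine-readable results list from [run_pipeline()].
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
validate_results <- function(results) {
  schema_path <- system.file("schema", "results-schema.json",
                             package = "deatonuv")
  if (schema_path == "") {
    schema_path <- file.path("inst", "schema", "results-schema.json")
  }
  schema <- jsonlite::read_json(schema_path)
  .validate_node(results, schema, "results")
  invisible(TRUE)
}

.validate_node <- function(node, schema, where) {
  type <- schema$type
  if (identical(type, "object")) {
    if (!is.list(node)) stop(where, " must be an object", call. = FALSE)
    for (key in unlist(schema$required)) {
      if (!key %in% names(node)) {
        stop(where, " is missing required key '", key, "'", call. = FALSE)
      }
    }
    for (key in names(schema$properties)) {
      if (key %in% names(node)) {
        .validate_node(node[[key]], schema$properties[[key]],
                       paste0(where, ".", key))
      }
    }
  } else if (identical(type, "number")) {
    if (!is.numeric(node) || length(node) != 1) {
      stop(where, " must be a single number", call. = FALSE)
    }
  } else if (identical(type, "integer")) {
    if (!is.numeric(node) || length(node) != 1 || node != round(node)) {
      stop(where, " must be a single integer", call. = FALSE)
    }
  } else if (identical(type, "boolean")) {
    if (!is.logical(node) || length(node) != 1) {
      stop(where, " must be a single boolean", call. = FALSE)
    }
  }
  invisible(TRUE)
}
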