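# Fixture builders used across the suite. Everything is generated in code.

toy_survey_path <- function() {
  system.file("extdata", "toy_survey.csv", package = "deatonuv")
}

# simulate + prepare in one step (no CPI: amounts already base-year)
make_prep <- function(n_clusters, hh_per_cluster, params = true_parameters(),
                      seed = 1, ...) {
  survey <- suppressMessages(
    simulate_survey(n_clusters, hh_per_cluster, params = params, seed = seed,
                    ...)
  )
  prep <- prepare_survey(survey)
  attr(prep, "truth") <- survey_truth(survey)
  prep
}

# hand-rolled prepared_survey with full control over lnv / share / cluster;
# covariates are filled with mild variation so the full design is identified
hand_prep <- function(cluster_id, ln_unit_value, budget_share,
                      ln_total_expenditure = NULL, seed = 99) {
  n <- length(cluster_id)
  set.seed(seed)
  total <- exp(if (is.null(ln_total_expenditure)) {
    rnorm(n, 10, 0.4)
  } else ln_total_expenditure)
  records <- data.frame(
    household_id = sprintf("h%03d", seq_len(n)),
    cluster_id = as.character(cluster_id),
    year = 2010,
    cig_expenditure = budget_share * total,
    cig_quantity = budget_share * total / exp(ln_unit_value),
    quantity_unit = "pack",
    total_expenditure = total,
    hh_size = sample(2:9, n, replace = TRUE),
    prop_adults = runif(n, 0.3, 0.8),
    prop_males = runif(n, 0.3, 0.8),
    educ_years_head = sample(0:14, n, replace = TRUE),
    age_head = runif(n, 25, 70),
    gender_head = sample(c("male", "female"), n, replace = TRUE),
    work_head = sample(c("employed", "not_employed"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  prepare_survey(records)
}

# bare cluster_averages object for direct between-stage tests
make_averages <- function(y1, y2, n_c = rep(2L, length(y1)),
                          n_c_plus = n_c) {
  structure(
    data.frame(cluster_id = sprintf("c%03d", seq_along(y1)),
               y1 = y1, y2 = y2, n_c = n_c, n_c_plus = n_c_plus),
    class = c("cluster_averages", "data.frame")
  )
}

# independent two-pass between/within sum-of-squares decomposition (oracle)
anova_ss_oracle <- function(y, cluster) {
  cl <- factor(cluster)
  grand <- mean(y)
  means <- tapply(y, cl, mean)
  counts <- tabulate(cl)
  between <- sum(counts * (means - grand)^2)
  within <- sum((y - means[as.integer(cl)])^2)
  C <- nlevels(cl)
  n <- length(y)
  f <- (between / (C - 1)) / (within / (n - C))
  list(between = between, within = within, total = sum((y - grand)^2),
       f = f, p = pf(f, C - 1, n - C, lower.tail = FALSE))
}
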