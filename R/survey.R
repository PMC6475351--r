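#' deatonuv: price elasticities from unit values
#'
#' Tools for estimating conditional price and expenditure elasticities of
#' demand from clustered household expenditure surveys with Deaton's
#' unit-value method. The pipeline runs: preprocessing ([prepare_survey()]),
#' a spatial price-variation check ([anova_unit_values()]), within-cluster
#' fixed-effects regressions ([fit_within()]), cluster residual averaging and
#' the measurement-error-corrected between-cluster slope
#' ([cluster_residual_averages()], [estimate_phi()]), and the quality-shading
#' correction that yields the elasticities ([estimate_elasticities()],
#' [deaton_fit()]). [simulate_survey()] generates clustered surveys with known
#' ground truth; [cluster_bootstrap()] and [trim_unit_values()] provide
#' inference and robustness checks; [run_pipeline()] orchestrates everything.
#'
#' @keywords internal
"_PACKAGE"

# Canonical column set of the survey CSV dialect.
.survey_columns <- c(
  "household_id", "cluster_id", "year", "cig_expenditure", "cig_quantity",
  "quantity_unit", "total_expenditure", "hh_size", "prop_adults",
  "prop_males", "educ_years_head", "age_head", "gender_head", "work_head"
)

.control_names <- c(
  "ln_hh_size", "prop_adults", "prop_males", "ln1p_educ_years",
  "ln_age_head", "gender_male", "work_employed"
)

#' Read a household expenditure survey from CSV
#'
#' Expects the canonical column set: `household_id`, `cluster_id`, `year`,
#' `cig_expenditure`, `cig_quantity`, `quantity_unit` (`"stick"` or `"pack"`),
#' `total_expenditure`, `hh_size`, `prop_adults`, `prop_males`,
#' `educ_years_head`, `age_head`, `gender_head` (`"male"`/`"female"`),
#' `work_head` (`"employed"`/`"not_employed"`). Missing values are empty
#' fields.
#'
#' @param path path to a CSV file.
#' @return a data.frame with one row per household.
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(household_id = "character",
                                       cluster_id = "character"),
                        na.strings = c("", "NA"))
  missing_cols <- setdiff(.survey_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("survey CSV is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df[, .survey_columns]
}

#' Build a CPI series for deflation
#'
#' @param index named numeric vector or list mapping year to CPI index value.
#' @param base_year year whose index defines the price level of the output.
#' @return an object of class `cpi_series`.
#' @examples
#' cpi_series(c(`2005` = 53.1, `2009` = 87.3, `2010` = 100), base_year = 2010)
#' @export
cpi_series <- function(index, base_year) {
  index <- unlist(index)
  if (is.null(names(index)) || any(names(index) == "")) {
    stop("`index` must be a named year -> value mapping", call. = FALSE)
  }
  if (any(!is.finite(index)) || any(index <= 0)) {
    stop("CPI index values must be positive and finite", call. = FALSE)
  }
  base_year <- as.character(base_year)
  if (!base_year %in% names(index)) {
    stop("base year ", base_year, " is not present in the CPI series",
         call. = FALSE)
  }
  structure(list(index = index, base_year = base_year), class = "cpi_series")
}

#' @export
print.cpi_series <- function(x, ...) {
  cat("CPI series (base year ", x$base_year, "):\n", sep = "")
  print(x$index)
  invisible(x)
}

#' Deflate a nominal amount to base-year prices
#'
#' Multiplies by `cpi[base_year] / cpi[year]`, so amounts from a year with a
#' lower price level are scaled up.
#'
#' @param amount numeric vector of nominal currency amounts.
#' @param year survey year(s) of the amounts (recycled against `amount`).
#' @param cpi a [cpi_series()].
#' @return amounts expressed in base-year prices.
#' @export
deflate <- function(amount, year, cpi) {
  stopifnot(inherits(cpi, "cpi_series"))
  year <- as.character(year)
  bad <- setdiff(unique(year), names(cpi$index))
  if (length(bad) > 0) {
    stop("CPI series has no entry for year(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  amount * unname(cpi$index[cpi$base_year] / cpi$index[year])
}

#' Convert cigarette quantities recorded in sticks to packs
#'
#' @param quantity positive numeric quantity in sticks.
#' @param pack_size cigarettes per pack (20 in Uganda).
#' @return quantity in packs.
#' @export
convert_sticks_to_packs <- function(quantity, pack_size = 20) {
  if (any(!is.finite(quantity)) || any(quantity <= 0)) {
    stop("stick quantities must be positive", call. = FALSE)
  }
  quantity / pack_size
}

#' Convert expenditures recalled over other periods to weekly amounts
#'
#' Convention used: annual recalls are divided by 52, 30-day recalls by 30/7.
#'
#' @param amount numeric amounts.
#' @param recall one of `"week"`, `"month30"`, `"year"`.
#' @return weekly-equivalent amounts.
#' @export
to_weekly <- function(amount, recall = c("week", "month30", "year")) {
  recall <- match.arg(recall)
  switch(recall,
         week = amount,
         month30 = amount / (30 / 7),
         year = amount / 52)
}

#' Unit value of cigarettes for a household
#'
#' Expenditure on cigarettes divided by quantity purchased (in packs): the
#' household-level price proxy.
#'
#' @param cig_expenditure positive expenditure over the recall period.
#' @param cig_quantity positive quantity in packs.
#' @return currency per pack.
#' @export
compute_unit_value <- function(cig_expenditure, cig_quantity) {
  if (any(!is.finite(cig_expenditure)) || any(cig_expenditure <= 0)) {
    stop("unit values require positive cigarette expenditure", call. = FALSE)
  }
  if (any(!is.finite(cig_quantity)) || any(cig_quantity <= 0)) {
    stop("unit values require positive cigarette quantity", call. = FALSE)
  }
  cig_expenditure / cig_quantity
}

#' Keep households that reported positive cigarette expenditure
#'
#' The survey cannot distinguish true zero expenditures from missing
#' information, so estimation is restricted to households reporting a positive
#' cigarette expenditure; the resulting elasticities are conditional on
#' smoking. Records with positive expenditure but a missing or non-positive
#' quantity cannot yield a unit value and are dropped with a warning.
#'
#' @param records data.frame in the [read_survey()] layout.
#' @return the smoking subsample; attribute `exclusions` carries the counts of
#'   non-positive-expenditure rows and of invalid-quantity rows removed.
#' @export
filter_positive_expenditure <- function(records) {
  pos <- !is.na(records$cig_expenditure) & records$cig_expenditure > 0
  n_nonpos <- sum(!pos)
  kept <- records[pos, , drop = FALSE]
  bad_q <- is.na(kept$cig_quantity) | kept$cig_quantity <= 0
  if (any(bad_q)) {
    warning(sum(bad_q), " record(s) with positive cigarette expenditure but ",
            "missing/non-positive quantity dropped (no unit value): ",
            paste(utils::head(kept$household_id[bad_q], 5), collapse = ", "),
            call. = FALSE)
    kept <- kept[!bad_q, , drop = FALSE]
  }
  if (nrow(kept) == 0) {
    stop("no smoking households: every record has non-positive or invalid ",
         "cigarette expenditure/quantity", call. = FALSE)
  }
  attr(kept, "exclusions") <- c(non_positive_expenditure = n_nonpos,
                                invalid_quantity = sum(bad_q))
  kept
}

#' Regression-ready household control vector
#'
#' Fixed column order: ln(household size), proportion of adults, proportion of
#' males, ln(1 + years of schooling of head), ln(age of head), male-head dummy,
#' employed-head dummy. Size, education and age enter in natural logarithms;
#' education uses ln(1 + years) so heads with no schooling are retained.
#'
#' @param records data.frame with the covariate columns of [read_survey()].
#' @return numeric matrix with one row per household.
#' @export
build_controls <- function(records) {
  if (any(!is.finite(records$age_head)) || any(records$age_head <= 0)) {
    stop("age_head must be positive for all households", call. = FALSE)
  }
  if (any(!is.finite(records$hh_size)) || any(records$hh_size < 1)) {
    stop("hh_size must be >= 1 for all households", call. = FALSE)
  }
  Z <- cbind(
    ln_hh_size = log(records$hh_size),
    prop_adults = records$prop_adults,
    prop_males = records$prop_males,
    ln1p_educ_years = log1p(records$educ_years_head),
    ln_age_head = log(records$age_head),
    gender_male = as.numeric(records$gender_head == "male"),
    work_employed = as.numeric(records$work_head == "employed")
  )
  rownames(Z) <- records$household_id
  Z
}

.check_record_invariants <- function(records) {
  with(records, {
    if (any(total_expenditure <= 0)) {
      stop("total_expenditure must be positive", call. = FALSE)
    }
    if (any(cig_expenditure > total_expenditure)) {
      stop("cig_expenditure exceeds total_expenditure for household(s): ",
           paste(utils::head(household_id[cig_expenditure > total_expenditure], 5),
                 collapse = ", "), call. = FALSE)
    }
    if (any(prop_adults < 0 | prop_adults > 1, na.rm = TRUE) ||
        any(prop_males < 0 | prop_males > 1, na.rm = TRUE)) {
      stop("prop_adults and prop_males must lie in [0, 1]", call. = FALSE)
    }
  })
  invisible(records)
}

#' Preprocess a survey for estimation
#'
#' Applies, in order: the positive-expenditure filter, stick-to-pack
#' conversion, CPI deflation of all monetary amounts to base-year prices,
#' unit-value and budget-share construction, and assembly of the control
#' matrix. Rows with a missing value in any regressor are dropped with a
#' logged count.
#'
#' @param records data.frame from [read_survey()] or [simulate_survey()].
#' @param cpi optional [cpi_series()]; when `NULL` amounts are assumed to be
#'   in base-year prices already.
#' @param pack_size cigarettes per pack used for stick conversion.
#' @return a `prepared_survey`: the filtered data.frame augmented with
#'   `unit_value`, `ln_unit_value`, `budget_share`, `ln_total_expenditure`
#'   and the control columns; attributes `controls` (column names) and
#'   `exclusions` (counts removed at each step).
#' @export
prepare_survey <- function(records, cpi = NULL, pack_size = 20) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.survey_columns, names(records))
  if (length(missing_cols) > 0) {
    stop("survey is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- filter_positive_expenditure(records)
  exclusions <- attr(records, "exclusions")
  .check_record_invariants(records)

  is_stick <- records$quantity_unit == "stick"
  records$cig_quantity[is_stick] <-
    convert_sticks_to_packs(records$cig_quantity[is_stick], pack_size)
  records$quantity_unit <- "pack"

  if (!is.null(cpi)) {
    records$cig_expenditure <- deflate(records$cig_expenditure, records$year, cpi)
    records$total_expenditure <- deflate(records$total_expenditure, records$year, cpi)
  }

  records$unit_value <- compute_unit_value(records$cig_expenditure,
                                           records$cig_quantity)
  records$ln_unit_value <- log(records$unit_value)
  records$budget_share <- records$cig_expenditure / records$total_expenditure
  records$ln_total_expenditure <- log(records$total_expenditure)

  Z <- build_controls(records)
  records <- cbind(records, Z)

  used <- c("ln_unit_value", "budget_share", "ln_total_expenditure",
            .control_names)
  complete <- stats::complete.cases(records[, used])
  if (any(!complete)) {
    message(sum(!complete), " household(s) dropped for missing regressors")
  }
  exclusions <- c(exclusions, missing_regressors = sum(!complete))
  records <- records[complete, , drop = FALSE]
  if (nrow(records) == 0) stop("no complete households remain", call. = FALSE)

  rownames(records) <- NULL
  structure(records,
            controls = .control_names,
            exclusions = exclusions,
            class = c("prepared_survey", "data.frame"))
}

#' Summary statistics of a prepared survey
#'
#' Mirrors the descriptive table of a unit-value study: mean cigarette budget
#' share (per cent), mean unit value per pack, mean weekly quantity in packs,
#' mean total household expenditure, covariate means, the number of
#' households, the number of effective clusters (clusters containing at least
#' one smoking household) and households per effective cluster.
#'
#' @param prep a `prepared_survey`.
#' @return a one-row data.frame of class `survey_summary`.
#' @export
summarize_survey <- function(prep) {
  stopifnot(inherits(prep, "prepared_survey"), nrow(prep) > 0)
  n <- nrow(prep)
  n_clusters <- length(unique(prep$cluster_id))
  out <- data.frame(
    n_households = n,
    n_clusters = n_clusters,
    households_per_cluster = n / n_clusters,
    mean_budget_share_pct = 100 * mean(prep$budget_share),
    mean_unit_value = mean(prep$unit_value),
    mean_quantity_packs = mean(prep$cig_quantity),
    mean_total_expenditure = mean(prep$total_expenditure),
    mean_hh_size = mean(prep$hh_size),
    mean_age_head = mean(prep$age_head),
    pct_male_head = 100 * mean(prep$gender_head == "male"),
    pct_adults = 100 * mean(prep$prop_adults),
    pct_males = 100 * mean(prep$prop_males),
    mean_educ_years = mean(prep$educ_years_head),
    pct_employed_head = 100 * mean(prep$work_head == "employed")
  )
  class(out) <- c("survey_summary", "data.frame")
  out
}

#' @export
print.survey_summary <- function(x, digits = 2, ...) {
  cat("Survey summary (", x$n_households, " households, ", x$n_clusters,
      " effective clusters, ", round(x$households_per_cluster, digits),
      " households/cluster)\n", sep = "")
  df <- as.data.frame(x)
  print(round(t(df), digits))
  invisible(x)
}

#' Percentage change between two values
#'
#' @param from starting value (non-zero).
#' @param to ending value.
#' @return `100 * (to - from) / from`.
#' @export
pct_change <- function(from, to) {
  stopifnot(all(from != 0))
  100 * (to - from) / from
}
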