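test_that("stick-to-pack conversion divides by the pack size", {
  expect_equal(convert_sticks_to_packs(40), 2.0)
  expect_equal(convert_sticks_to_packs(20), 1.0)
  expect_equal(convert_sticks_to_packs(1), 0.05)
  expect_equal(convert_sticks_to_packs(c(10, 30)), c(0.5, 1.5))
  expect_error(convert_sticks_to_packs(0), "positive")
  expect_error(convert_sticks_to_packs(-5), "positive")
})

test_that("CPI deflation rescales by the base-year index ratio", {
  cpi <- cpi_series(c(`2005` = 50, `2010` = 100), base_year = 2010)
  expect_equal(deflate(100, 2010, cpi), 100)   # identity at base year
  expect_equal(deflate(100, 2005, cpi), 200)   # price level doubled since
  expect_equal(deflate(0, 2005, cpi), 0)
  expect_error(deflate(100, 1999, cpi), "1999")
  expect_error(cpi_series(c(`2005` = 50), base_year = 2010), "base year")
  expect_error(cpi_series(c(`2005` = -1, `2010` = 100), 2010), "positive")
})

test_that("recall-period conversion maps annual and 30-day amounts to weekly", {
  expect_equal(to_weekly(52, "year"), 1)
  expect_equal(to_weekly(30, "month30"), 7)
  expect_equal(to_weekly(10, "week"), 10)
})

test_that("unit value is expenditure per pack and inverts exactly", {
  expect_equal(compute_unit_value(2000, 1), 2000)
  expect_equal(compute_unit_value(3000, convert_sticks_to_packs(40)), 1500)
  expect_error(compute_unit_value(0, 1), "positive")
  expect_error(compute_unit_value(100, 0), "positive")

  prep <- suppressWarnings(prepare_survey(read_survey(toy_survey_path())))
  # v * q == expenditure to machine precision (quantities now in packs)
  expect_equal(prep$unit_value * prep$cig_quantity, prep$cig_expenditure,
               tolerance = 1e-15)
})

test_that("deflation commutes with unit conversion on the unit value", {
  cpi <- cpi_series(c(`2005` = 53.1, `2010` = 100), base_year = 2010)
  exp_ <- 3000; sticks <- 40
  a <- deflate(exp_, 2005, cpi) / convert_sticks_to_packs(sticks)
  b <- deflate(exp_ / convert_sticks_to_packs(sticks), 2005, cpi)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("positive-expenditure filter keeps smokers and is idempotent", {
  survey <- read_survey(toy_survey_path())
  expect_warning(kept <- filter_positive_expenditure(survey),
                 "missing/non-positive quantity")
  # 16 rows: 2 zero-expenditure, 1 positive-expenditure-missing-quantity
  expect_equal(nrow(kept), 13)
  excl <- attr(kept, "exclusions")
  expect_equal(unname(excl["non_positive_expenditure"]), 2)
  expect_equal(unname(excl["invalid_quantity"]), 1)
  expect_false("h012" %in% kept$household_id)

  again <- filter_positive_expenditure(kept)
  attr(again, "exclusions") <- attr(kept, "exclusions") <- NULL
  expect_equal(again, kept)

  none <- survey[survey$cig_expenditure == 0 & !is.na(survey$cig_expenditure), ]
  expect_error(filter_positive_expenditure(none), "no smoking households")
})

test_that("control vector has the documented order and log transforms", {
  rec <- data.frame(household_id = "h1", hh_size = 1, prop_adults = 0.5458,
                    prop_males = 0.53, educ_years_head = 0,
                    age_head = exp(1), gender_head = "male",
                    work_head = "employed")
  Z <- build_controls(rec)
  expect_identical(colnames(Z),
                   c("ln_hh_size", "prop_adults", "prop_males",
                     "ln1p_educ_years", "ln_age_head", "gender_male",
                     "work_employed"))
  expect_equal(unname(Z[1, ]),
               c(0, 0.5458, 0.53, 0, 1, 1, 1))
  rec$age_head <- -1
  expect_error(build_controls(rec), "age_head")
})

test_that("preparation builds shares, logs and controls on the smoker sample", {
  cpi <- cpi_series(c(`2005` = 53.1, `2010` = 100), base_year = 2010)
  prep <- suppressWarnings(
    prepare_survey(read_survey(toy_survey_path()), cpi = cpi)
  )
  expect_s3_class(prep, "prepared_survey")
  expect_true(all(prep$budget_share > 0 & prep$budget_share <= 1))
  expect_equal(prep$ln_unit_value, log(prep$unit_value))
  expect_equal(prep$ln_total_expenditure, log(prep$total_expenditure))
  expect_true(all(prep$quantity_unit == "pack"))
  # budget share is unaffected by deflation (both amounts rescaled alike)
  prep0 <- suppressWarnings(prepare_survey(read_survey(toy_survey_path())))
  expect_equal(prep$budget_share, prep0$budget_share, tolerance = 1e-12)
  # deflation scaled the unit values up (2005 price level below base year)
  expect_equal(prep$unit_value, prep0$unit_value * 100 / 53.1,
               tolerance = 1e-12)
})

test_that("summary statistics compute the descriptive table", {
  prep <- make_prep(10, 3, seed = 5)
  one <- prep[1, , drop = FALSE]
  s1 <- summarize_survey(one)
  expect_equal(s1$n_households, 1)
  expect_equal(s1$mean_unit_value, one$unit_value)
  expect_equal(s1$mean_budget_share_pct, 100 * one$budget_share)

  s <- summarize_survey(prep)
  expect_equal(s$n_households, 30)
  expect_equal(s$n_clusters, 10)
  expect_equal(s$households_per_cluster, 3)
})

test_that("generated mean budget share is recovered at n = 10,000", {
  prep <- make_prep(2000, 5, seed = 8)
  params <- attr(prep, "truth")$params
  se <- sd(prep$budget_share) / sqrt(nrow(prep))
  expect_lt(abs(mean(prep$budget_share) - params$target_mean_share), 3 * se)
})

test_that("percentage change helper matches hand arithmetic", {
  expect_equal(pct_change(100, 150), 50)
  expect_equal(pct_change(200, 100), -50)
  expect_error(pct_change(0, 1))
})
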