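test_that("cohort CSV round-trips through a codebook", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "survey.csv")
  raw <- data.frame(
    hhid = c("A1", "A2", "A3"),
    community = c("north", "north", "south"),
    zlen = c(-1.5, 0.2, -2.4),
    age = c(30L, 45L, 55L),
    sex = c(0L, 1L, 0L),
    mom_school = c(4, 9, 0),
    inc = c(1200, 5000, 800),
    cur = c("XTS", "XTS", "XTS"),
    crowding = c(2.5, 1.2, 4),
    water = c("yes", "yes", "no"),
    toilet = c("no", "yes", "no"),
    died = c(0, 0, 1),
    elec = c(1, 1, 0),
    floor = c(1, 0, 1),
    fuel = c(1, 0, 1),
    has_radio = c("yes", "no", "maybe"),
    has_tv = c(0, 1, 0)
  )
  write.csv(raw, csv, row.names = FALSE)
  codebook <- list(
    columns = list(household_id = "hhid", site = "community", haz = "zlen",
                   child_age_months = "age", child_sex = "sex",
                   maternal_education_years = "mom_school",
                   income_local = "inc", currency = "cur",
                   people_per_room = "crowding", improved_water = "water",
                   improved_sanitation = "toilet", any_child_died = "died",
                   electricity = "elec", natural_flooring = "floor",
                   solid_cooking_fuel = "fuel"),
    assets = list(radio = "has_radio", tv = "has_tv"),
    indicator_coding = list(yes = 1, no = 0),
    currency_table = list(date = "2010-01-01", rates = list(XTS = 0.5))
  )
  expect_warning(cohort <- read_cohort(csv, codebook),
                 "unparseable")  # "maybe" in has_radio
  expect_s3_class(cohort, "wami_cohort")
  expect_equal(nrow(cohort), 3)
  expect_equal(asset_names(cohort), c("radio", "tv"))
  expect_equal(cohort$radio, c(1, 0, NA))
  expect_equal(cohort$improved_water, c(1, 1, 0))
  expect_equal(cohort$income_usd, c(600, 2500, 400))

  # round-trip: write then re-read with an identity codebook
  out <- file.path(dir, "roundtrip.csv")
  write_cohort(cohort, out)
  cb2 <- codebook
  cb2$columns <- as.list(stats::setNames(
    names(codebook$columns), names(codebook$columns)))
  cb2$assets <- list(radio = "radio", tv = "tv")
  again <- read_cohort(out, cb2)
  for (f in c("household_id", "site", "haz", "maternal_education_years",
              "income_local", "people_per_room", "improved_water")) {
    expect_identical(again[[f]], cohort[[f]])
  }
  expect_identical(again$radio, cohort$radio)
})

test_that("read_cohort enforces its column contract", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "bad.csv")
  write.csv(data.frame(hhid = "A1", community = "north"), csv,
            row.names = FALSE)
  codebook <- list(columns = list(household_id = "hhid",
                                  site = "community", haz = "zlen"),
                   assets = list())
  expect_error(read_cohort(csv, codebook), "zlen")
  expect_error(read_cohort(csv, list(columns = list(household_id = "hhid"),
                                     assets = list())),
               "haz")
  # duplicate household ids are a hard error
  write.csv(data.frame(hhid = c("A1", "A1"), community = "north",
                       zlen = c(0, 1)), csv, row.names = FALSE)
  expect_error(read_cohort(csv, codebook), "duplicate")
})

test_that("the shipped example survey reads cleanly", {
  csv <- system.file("extdata", "example_survey.csv", package = "wamindex")
  cb <- system.file("extdata", "example_codebook.yaml", package = "wamindex")
  cohort <- read_cohort(csv, cb)
  expect_equal(nrow(cohort), 6)
  expect_setequal(asset_names(cohort),
                  c("radio", "tv", "fridge", "mobile_phone"))
  expect_equal(cohort$income_usd, cohort$income_local * 0.02)
  expect_equal(sum(is_stunted(cohort$haz)), 2)
})

test_that("income converts to USD by the exchange-rate table", {
  ct <- currency_table(c(USD = 1.0, XXX = 0.2), date = "2010-01-01")
  expect_equal(convert_income_usd(100, "USD", ct), 100)
  expect_equal(convert_income_usd(500, "XXX", ct), 100)
  expect_equal(convert_income_usd(0, "XXX", ct), 0)
  expect_error(convert_income_usd(10, "ZZZ", ct), "USD")  # lists known codes
  expect_error(currency_table(c(USD = -1)), "positive")
})

test_that("anthropometric filter removes missing then extreme HAZ", {
  cohort <- make_test_cohort(10, haz = c(NA, 7, -6.5, seq(-3, 2, length.out = 7)))
  res <- filter_anthropometry(cohort, haz_abs_limit = 6)
  expect_equal(nrow(res$cohort), 7)
  expect_equal(res$exclusions$missing_haz, 1)
  expect_equal(res$exclusions$extreme_haz, 2)
  # counts always sum to input minus output
  expect_equal(res$exclusions$missing_haz + res$exclusions$extreme_haz,
               nrow(cohort) - nrow(res$cohort))
  # idempotent
  res2 <- filter_anthropometry(res$cohort, haz_abs_limit = 6)
  expect_equal(nrow(res2$cohort), nrow(res$cohort))
  expect_equal(res2$exclusions$missing_haz + res2$exclusions$extreme_haz, 0)
  expect_identical(res2$cohort$haz, res$cohort$haz)
  # boundary: |HAZ| equal to the limit is retained
  keep_at_limit <- make_test_cohort(3, haz = c(6, -6, 0))
  expect_equal(nrow(filter_anthropometry(keep_at_limit, 6)$cohort), 3)
  # all-missing HAZ empties the cohort
  all_na <- make_test_cohort(4, haz = rep(NA_real_, 4))
  res3 <- filter_anthropometry(all_na)
  expect_equal(nrow(res3$cohort), 0)
  expect_equal(res3$exclusions$missing_haz, 4)
})

test_that("stunting is HAZ strictly below -2", {
  expect_equal(is_stunted(c(-2.01, -2.00, 0.5, -5)), c(1L, 0L, 0L, 1L))
  expect_error(is_stunted(NA_real_), "missing")
})
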