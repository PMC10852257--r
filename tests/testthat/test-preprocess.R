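# Aggregation, yield disaggregation, correlation filter, transaction encoding.

test_that("daily records aggregate to one monthly mean per (zone, year, month)", {
  # constructed 30-day month with values 1..30 in every attribute
  daily <- tibble::tibble(
    zone = "z",
    date = seq(as.Date("2003-04-01"), as.Date("2003-04-30"), by = "day"),
    Tmin = 1:30, Tmax = 1:30, Umin = 1:30, Umax = 1:30,
    RR = 1:30, Sun = 1:30, ET = 1:30
  )
  monthly <- aggregate_daily_to_monthly(daily)
  expect_equal(nrow(monthly), 1)
  expect_equal(monthly$year, 2003L)
  expect_equal(monthly$month, 4L)
  for (a in c("Tmin", "Tmax", "Umin", "Umax", "RR", "Sun", "ET")) {
    expect_equal(monthly[[a]], 15.5)
  }

  # a month with one day passes through unchanged
  one <- daily[1, ]
  m1 <- aggregate_daily_to_monthly(one)
  expect_equal(m1$ET, 1)

  # aggregating already-monthly data (one day per month) is the identity
  twelve <- dplyr::mutate(daily[1:12, ],
                          date = as.Date(sprintf("2003-%02d-15", 1:12)))
  m12 <- aggregate_daily_to_monthly(twelve)
  expect_equal(nrow(m12), 12)
  expect_equal(m12$ET, as.numeric(1:12))

  # non-numeric attribute -> parse error naming the attribute
  bad <- dplyr::mutate(daily, ET = as.character(ET))
  bad$ET[3] <- "oops"
  expect_error(aggregate_daily_to_monthly(bad), "ET")
})

test_that("fully missing months are dropped with a warning", {
  daily <- tibble::tibble(
    zone = "z",
    date = as.Date(c("2003-04-01", "2003-04-02", "2003-05-01")),
    Tmin = c(10, 12, NA), Tmax = c(20, 22, NA), Umin = c(40, 42, NA),
    Umax = c(80, 82, NA), RR = c(1, 2, NA), Sun = c(6, 7, NA), ET = c(3, 4, NA)
  )
  expect_warning(monthly <- aggregate_daily_to_monthly(daily), "dropping")
  expect_equal(nrow(monthly), 1)
  expect_equal(monthly$Tmin, 11)
})

test_that("attach_monthly_yield disaggregates annual yield as annual / 12", {
  monthly <- tidyr::expand_grid(zone = "z", year = 2000L, month = 1:12) |>
    dplyr::mutate(ET = 1)
  yields <- tibble::tibble(zone = "z", year = 2000L, annual_yield_kg_ha = 1200)
  out <- attach_monthly_yield(monthly, yields)
  expect_equal(out$yield_kg_ha, rep(100, 12))
  expect_equal(sum(out$yield_kg_ha), 1200)   # conservation over the year

  zero <- attach_monthly_yield(monthly,
                               dplyr::mutate(yields, annual_yield_kg_ha = 0))
  expect_equal(zero$yield_kg_ha, rep(0, 12))

  expect_error(
    attach_monthly_yield(dplyr::mutate(monthly, year = 2001L), yields),
    "z/2001"
  )
})

test_that("correlation filter drops the redundant humidity predictor", {
  rec <- generate_monthly_records(benin_profile(), 1995, 2020, seed = 8)
  cf <- correlation_filter(rec, threshold = 0.8)
  expect_equal(cf$dropped, "Umin")
  expect_setequal(cf$retained, c("Tmin", "Tmax", "Umax", "RR", "Sun", "ET"))
  # 7 attributes remain: 6 predictors + yield
  expect_equal(length(cf$retained) + 1, 7)
  expect_true(is.matrix(cf$matrix))
  expect_gt(abs(cf$matrix["Umin", "Umax"]), 0.8)
})

test_that("independent predictors survive; duplicated columns lose one member", {
  set.seed(99)
  n <- 500
  rec <- tibble::tibble(
    zone = "z", year = 2000L, month = 1L,
    Tmin = rnorm(n), Tmax = rnorm(n), Umin = runif(n, 0, 100),
    Umax = runif(n, 0, 100), RR = rexp(n), Sun = runif(n, 0, 12),
    ET = rnorm(n, 4), yield_kg_ha = rexp(n, 1 / 500)
  )
  cf <- correlation_filter(rec, 0.8)
  expect_length(cf$dropped, 0)

  dup <- dplyr::mutate(rec, Sun = ET)    # r = 1 pair
  cf2 <- correlation_filter(dup, 0.8)
  expect_equal(cf2$dropped, "ET")        # Sun precedes ET in keep-priority
  expect_true("Sun" %in% cf2$retained)

  const <- dplyr::mutate(rec, RR = 5)
  expect_warning(cf3 <- correlation_filter(const, 0.8), "zero-variance")
  expect_true("RR" %in% cf3$retained)
})

test_that("to_transactions encodes one item per retained attribute", {
  th <- benin_thresholds()
  rec <- generate_monthly_records(sudanian_profile(), 1995, 2020, seed = 4)
  tx <- to_transactions(rec, th,
                        attributes = c("Tmin", "Tmax", "Umax", "RR", "Sun", "ET"))
  expect_equal(nrow(tx), 312)
  expect_true(all(lengths(tx$items) == 7))  # 6 predictors + Yield
  attrs <- sort(c("Tmin", "Tmax", "Umax", "RR", "Sun", "ET", "Yield"))
  for (t in tx$items[1:20]) {
    expect_equal(sort(sub("=.*", "", t)), attrs)  # no duplicate attribute
  }

  # item frequencies equal direct column tabulation
  et_row <- dplyr::filter(th, zone == "Sudanian", attribute == "ET")
  expected <- table(discretize(rec$ET, et_row$low_cut, et_row$high_cut))
  mined <- table(sub("ET=", "", grep("^ET=", unlist(tx$items), value = TRUE)))
  expect_equal(as.vector(expected[sort(names(expected))]),
               as.vector(mined[sort(names(expected))]))

  expect_error(
    to_transactions(dplyr::mutate(rec, zone = "Atlantis"), th),
    "Atlantis"
  )
})
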