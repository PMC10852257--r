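# Synthetic generator: record counts, determinism, moment fidelity,
# planted rules.

test_that("generate_monthly_records emits 12 records per year per zone", {
  prof <- sudanian_profile()
  expect_equal(nrow(generate_monthly_records(prof, 1995, 2020, seed = 1)), 312)
  expect_equal(nrow(generate_monthly_records(prof, 2000, 2000, seed = 1)), 12)
  full <- generate_monthly_records(benin_profile(), 1995, 2020, seed = 1)
  expect_equal(nrow(full), 936)
  expect_error(generate_monthly_records(prof, 2001, 2000, seed = 1), "start_year")
})

test_that("identical seeds give byte-identical CSV output, different seeds differ", {
  prof <- benin_profile()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_climate_csv(generate_monthly_records(prof, 2000, 2004, seed = 42), f1)
  write_climate_csv(generate_monthly_records(prof, 2000, 2004, seed = 42), f2)
  write_climate_csv(generate_monthly_records(prof, 2000, 2004, seed = 43), f3)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("sample moments match the profile within 3 standard errors", {
  prof <- sudanian_profile()
  rec <- generate_monthly_records(prof, 1995, 2020, seed = 202)
  n <- nrow(rec)
  for (attr in c("ET", "RR", "Tmin", "Umax", "Yield")) {
    row <- dplyr::filter(prof, attribute == attr)
    x <- rec[[ifelse(attr == "Yield", "yield_kg_ha", attr)]]
    se_mean <- row$sd / sqrt(n)
    expect_lt(abs(mean(x) - row$mean), 3 * se_mean)
    # bounds respected
    b <- agrorules:::attribute_bounds(attr)
    expect_true(all(x >= b$lower & x <= b$upper))
  }
  expect_true(all(rec$Umin >= 0 & rec$Umin <= 100 & rec$Umin <= rec$Umax))
})

test_that("correlated Umin mechanism reproduces the >0.8 redundancy", {
  rec <- generate_monthly_records(benin_profile(), 1995, 2020, seed = 3)
  expect_gt(stats::cor(rec$Umin, rec$Umax), 0.8)
})

test_that("generate_daily_records covers every calendar day", {
  prof <- sudanian_profile()
  daily <- generate_daily_records(prof, 2001, 2001, seed = 9)
  expect_equal(nrow(daily), 365)
  leap <- generate_daily_records(prof, 2000, 2000, seed = 9)
  expect_equal(nrow(leap), 366)
})

test_that("plant_rule hits the planted counts exactly", {
  th <- benin_thresholds()
  rec <- planted_sudanian()
  n <- nrow(rec)
  expect_equal(n, 312)

  tx <- to_transactions(rec, th)
  target <- c("ET=low", "Tmin=medium", "Umax=high", "Yield=high")
  full_count <- sum(vapply(tx$items, function(t) all(target %in% t), logical(1)))
  ante_count <- sum(vapply(tx$items, function(t) all(target[1:3] %in% t), logical(1)))
  expect_equal(full_count, 78)            # ceiling(0.25 * 312)
  expect_equal(ante_count, 78)            # confidence 1 => antecedent only with consequent
  # mined support of the planted rule equals planted count / n exactly
  its <- enumerate_bruteforce(tx$items, min_support_count = 2)
  key <- paste(sort(target), collapse = ";")
  expect_equal(its$support[its$itemset == key], 78 / 312)
})

test_that("plant_rule handles partial confidence and saturation", {
  th <- benin_thresholds()
  prof <- sudanian_profile()
  rec <- generate_monthly_records(prof, 1995, 2020, seed = 21)
  # support 1: every record carries the full itemset
  all_in <- plant_rule(rec, c("ET=low", "Tmin=medium"), "Yield=high",
                       target_support = 1, target_confidence = 1,
                       thresholds = th, seed = 2)
  tx <- to_transactions(all_in, th)
  target <- c("ET=low", "Tmin=medium", "Yield=high")
  expect_true(all(vapply(tx$items, function(t) all(target %in% t), logical(1))))

  # confidence 0.5: antecedent occurs twice as often as the full itemset
  half <- plant_rule(rec, c("ET=low", "Tmin=medium"), "Yield=high",
                     target_support = 0.25, target_confidence = 0.5,
                     thresholds = th, seed = 2)
  txh <- to_transactions(half, th)
  n <- nrow(rec)
  full_count <- sum(vapply(txh$items, function(t) all(target %in% t), logical(1)))
  ante_count <- sum(vapply(txh$items, function(t) all(target[1:2] %in% t), logical(1)))
  expect_equal(full_count, ceiling(0.25 * n))
  expect_lte(abs(full_count / ante_count - 0.5), 1 / n)
})

test_that("infeasible planted specs raise errors", {
  th <- benin_thresholds()
  rec <- generate_monthly_records(sudanian_profile(), 2000, 2001, seed = 1)
  expect_error(
    plant_rule(rec, "ET=low", "Yield=high", target_support = 0.5,
               target_confidence = 0.2, thresholds = th, seed = 1),
    "infeasible"
  )
  expect_error(
    plant_rule(rec, "Yield=low", "Yield=high", target_support = 0.2,
               target_confidence = 1, thresholds = th, seed = 1),
    "distinct"
  )
  expect_error(
    plant_rule(rec, "Banana=low", "Yield=high", target_support = 0.2,
               target_confidence = 1, thresholds = th, seed = 1),
    "Banana"
  )
})
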