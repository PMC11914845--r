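test_that("a noiseless linear series is fitted exactly with a collapsed band", {
  dates <- as.Date("2020-01-01") + seq(0, 57, by = 3)
  y <- 70 + 0.05 * as.numeric(dates - dates[1])
  co <- make_test_cohort(dates, weight = NA)
  co$records$weight_kg <- y
  fit <- fit_baseline(patient_series(co, "T01"), "weight")
  expect_equal(fit$slope, 0.05, tolerance = 1e-12)
  expect_equal(fit$intercept, 70, tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0)
  expect_equal(fit$band$lower, fit$band$fitted)
  expect_equal(fit$band$upper, fit$band$fitted)
  expect_length(flag_discrete_points(fit), 0)
  expect_length(flag_discrete_points(fit, method = "band"), 0)
})

test_that("a gross outlier is a discrete point at both criteria and methods", {
  dates <- as.Date("2021-06-01") + 0:30
  co <- make_test_cohort(dates, weight = 100)
  co$records$weight_kg <- c(rep(100, 15), 200, rep(100, 15)) +
    withr::with_seed(2, rnorm(31, 0, 0.5))
  ser <- patient_series(co, "T01")
  for (m in c("studentized", "band")) {
    for (a in c(0.05, 0.01)) {
      f <- fit_baseline(ser, "weight", alpha = a)
      expect_identical(flag_discrete_points(f, method = m), dates[16])
    }
  }
})

test_that("prediction and confidence bands match the lm oracle", {
  withr::with_seed(31, {
    for (i in 1:30) {
      k <- sample(10:40, 1)
      dates <- as.Date("2020-01-01") + sort(sample(0:120, k))
      y <- rnorm(k, 80 + 0.1 * as.numeric(dates - dates[1]), 3)
      co <- make_test_cohort(dates)
      co$records$dbp_mmhg <- y
      co$records$sbp_mmhg <- y + 70
      a <- sample(c(0.05, 0.01, 0.1), 1)
      for (btype in c("prediction", "confidence")) {
        f <- fit_baseline(patient_series(co, "T01"), "dbp", alpha = a,
                          band = btype)
        orc <- oracle_band(as.numeric(dates - dates[1]), y, alpha = a,
                           interval = btype)
        expect_equal(f$band$fitted, orc$fitted, tolerance = 1e-9)
        expect_equal(f$band$lower, orc$lower, tolerance = 1e-9)
        expect_equal(f$band$upper, orc$upper, tolerance = 1e-9)
      }
    }
  })
})

test_that("flags are nested in alpha and invariant to constant shifts", {
  withr::with_seed(17, {
    for (i in 1:20) {
      k <- sample(12:50, 1)
      dates <- as.Date("2020-01-01") + sort(sample(0:200, k))
      y <- rnorm(k, 90, 4) + rexp(k) * rbinom(k, 1, 0.1) * 10
      co <- make_test_cohort(dates)
      co$records$dbp_mmhg <- y
      co$records$sbp_mmhg <- y + 80
      ser <- patient_series(co, "T01")
      for (m in c("studentized", "band")) {
        f05 <- flag_discrete_points(fit_baseline(ser, "dbp", 0.05), method = m)
        f01 <- flag_discrete_points(fit_baseline(ser, "dbp", 0.01), method = m)
        expect_true(all(f01 %in% f05))
        # wider band contains the narrower one pointwise
        b05 <- fit_baseline(ser, "dbp", 0.05)$band
        b01 <- fit_baseline(ser, "dbp", 0.01)$band
        expect_true(all(b01$lower <= b05$lower + 1e-12))
        expect_true(all(b01$upper >= b05$upper - 1e-12))
      }
      co2 <- co
      co2$records$dbp_mmhg <- co2$records$dbp_mmhg + 37.5
      f_shift <- flag_discrete_points(fit_baseline(patient_series(co2, "T01"), "dbp", 0.05))
      f_orig <- flag_discrete_points(fit_baseline(ser, "dbp", 0.05))
      expect_identical(f_shift, f_orig)
    }
  })
})

test_that("the cohort-level path reproduces the per-patient path", {
  co <- generate_cohort(test_config(n = 60, seed = 14))
  for (m in c("studentized", "band")) {
    fl <- discretize_cohort(co, method = m)
    ref <- suppressWarnings(do.call(rbind, lapply(co$patients$patient_id, function(p) {
      discretize_patient(patient_series(co, p), method = m)
    })))
    x <- merge(fl, ref, by = c("patient_id", "variable", "alpha"))
    expect_identical(nrow(x), nrow(fl))
    expect_identical(x$category.x, x$category.y)
    expect_identical(as.integer(x$n_discrete_points.x),
                     as.integer(x$n_discrete_points.y))
    expect_identical(x$dates.x, x$dates.y)
  }
})

test_that("only excursions inside the assessment window set a category", {
  hf <- as.Date("2021-09-01")
  dates <- seq(hf - 60, hf - 1, by = 1)
  spike_at <- function(d) {
    co <- make_test_cohort(dates, hf_date = hf, sbp = 200)
    co$records$dbp_mmhg <- 80 + withr::with_seed(4, rnorm(60, 0, 1))
    co$records$dbp_mmhg[dates == d] <- 120
    discretize_patient(patient_series(co, "T01"))
  }
  inside <- spike_at(hf - 15)   # window is [hf - 15, hf - 1]
  expect_identical(
    inside$category[inside$variable == "dbp" & inside$alpha == 0.05], "abnormal")
  # with steady sbp the derived pulse pressure inherits the dbp excursion,
  # but the untouched vitals stay normal
  expect_true(all(inside$category[inside$variable %in% c("weight", "urine", "sbp")] == "normal"))
  edge_out <- spike_at(hf - 16)
  expect_true(all(edge_out$category[edge_out$variable == "dbp"] == "normal"))
})

test_that("short series signal insufficiency and default to normal", {
  dates <- as.Date("2022-01-01") + 0:4
  co <- make_test_cohort(dates)
  expect_error(fit_baseline(patient_series(co, "T01"), "weight"),
               class = "pdhf_insufficient_data")
  fl <- discretize_patient(patient_series(co, "T01"))
  expect_true(all(fl$category == "normal"))
  expect_true(all(fl$insufficient))
  flc <- discretize_cohort(co)
  expect_true(all(flc$category == "normal"))
  expect_true(all(flc$insufficient))
})

test_that("a window outside the observed range raises the empty-window signal", {
  dates <- as.Date("2022-01-01") + 0:29
  co <- make_test_cohort(dates)
  expect_warning(
    discretize_patient(patient_series(co, "T01"),
                       window = c(as.Date("2023-01-01"), as.Date("2023-01-15"))),
    class = "pdhf_empty_window")
})

test_that("per-point flag rate under the null model is close to alpha", {
  # trend + i.i.d. Gaussian noise; studentized rule has exact per-point
  # level, the included-point band rule is slightly conservative
  co <- generate_cohort(cohort_config(
    n_patients = 300, hf_prevalence = 0, follow_up_days = c(min = 60, max = 60),
    record_completeness = 1, seed = 23))
  fl <- discretize_cohort(co, window = "all")
  fw <- fl[fl$variable == "weight" & fl$alpha == 0.05, ]
  rate <- fw$n_discrete_points / fw$n_obs
  se <- sd(rate) / sqrt(nrow(fw))
  expect_lt(abs(mean(rate) - 0.05), 3 * se)
  flb <- discretize_cohort(co, window = "all", method = "band")
  fb <- flb[flb$variable == "weight" & flb$alpha == 0.05, ]
  rate_b <- mean(fb$n_discrete_points / fb$n_obs)
  expect_lt(rate_b, 0.055)
  expect_gt(rate_b, 0.030)
})
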