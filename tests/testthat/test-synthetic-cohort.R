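test_that("invalid configurations are rejected with the field named", {
  expect_error(cohort_config(hf_prevalence = 1.5), "hf_prevalence")
  expect_error(cohort_config(female_fraction = -0.1), "female_fraction")
  expect_error(cohort_config(follow_up_days = c(min = 200, max = 100)),
               "follow_up_days")
  expect_error(cohort_config(hf_window_days = 0), "hf_window_days")
  expect_error(cohort_config(baseline_levels = list(
    weight = c(mean = 60, between_sd = -1, within_sd = 1),
    urine = c(800, 400, 120), sbp = c(135, 15, 8), dbp = c(85, 10, 6))),
    "baseline_levels")
  expect_error(cohort_config(bp_noise_cor = 2), "bp_noise_cor")
})

test_that("generation is a pure function of the seed", {
  cfg <- test_config(n = 120, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c <- generate_cohort(test_config(n = 120, seed = 43))
  expect_false(identical(a, c))
  # the caller's RNG stream is untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_cohort(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("generated records satisfy the physical invariants", {
  co <- generate_cohort(test_config(n = 200, seed = 11))
  r <- co$records
  expect_true(all(r$weight_kg > 0))
  expect_true(all(r$urine_ml >= 0))
  expect_true(all(r$sbp_mmhg > r$dbp_mmhg))
  expect_true(all(r$dbp_mmhg > 0))
  expect_false(any(duplicated(paste(r$patient_id, r$date))))
  # dates inside each patient's follow-up, strictly increasing per patient
  p <- co$patients
  m <- merge(r, p[, c("patient_id", "enrollment_date", "follow_up_days")])
  expect_true(all(m$date >= m$enrollment_date))
  expect_true(all(m$date <= m$enrollment_date + m$follow_up_days - 1))
})

test_that("heart-failure dates sit in the last third with a full window", {
  co <- generate_cohort(test_config(n = 500, seed = 12))
  p <- co$patients[!is.na(co$patients$hf_date), ]
  expect_gt(nrow(p), 10)
  day <- as.integer(p$hf_date - p$enrollment_date) + 1L
  expect_true(all(day >= ceiling(2 * p$follow_up_days / 3)))
  expect_true(all(day <= p$follow_up_days))
  expect_true(all(day > 15))  # a complete 15-day progression window exists
})

test_that("female fraction and prevalence match the configuration", {
  cfg <- cohort_config(n_patients = 4000, hf_prevalence = 0.05,
                       follow_up_days = c(min = 60, max = 90),
                       record_completeness = 0.2, seed = 5)
  co <- generate_cohort(cfg)
  p <- co$patients
  se_f <- sqrt(0.6115 * (1 - 0.6115) / 4000)
  expect_lt(abs(mean(p$sex == "female") - 0.6115), 3 * se_f)
  se_h <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(mean(!is.na(p$hf_date)) - 0.05), 3 * se_h)
})

test_that("expected case count matches the binomial expectation", {
  # 6635 x 0.0071 = 47.1 expected cases; profile-level Monte Carlo
  cfg <- cohort_config(seed = NULL)
  counts <- withr::with_seed(99, {
    vapply(1:200, function(i) {
      sum(!is.na(pdhf:::.generate_profiles(cfg)$hf_date))
    }, numeric(1))
  })
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 6635 * 0.0071), 3 * se)
})

test_that("a zero planted effect leaves case and control flag rates alike", {
  cfg <- test_config(n = 800, seed = 21,
                     hf_effect = c(weight = 0, urine = 0, sbp = 0, dbp = 0))
  co <- generate_cohort(cfg)
  fl <- discretize_cohort(co)
  rows <- build_rows(co, fl, 0.05)
  r1 <- mean(rows$dbp_cat[rows$hf_label == 1] == "abnormal")
  r0 <- mean(rows$dbp_cat[rows$hf_label == 0] == "abnormal")
  n1 <- sum(rows$hf_label == 1); n0 <- sum(rows$hf_label == 0)
  pbar <- (r1 * n1 + r0 * n0) / (n1 + n0)
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n0))
  expect_lt(abs(r1 - r0), 3 * se + 1e-9)
})

test_that("a larger planted dbp effect raises the case flag rate", {
  rates <- withr::with_seed(7, {
    sapply(1:100, function(i) {
      s <- sample.int(1e6, 1)
      rate_at <- function(eff) {
        cfg <- cohort_config(n_patients = 150, hf_prevalence = 0.25,
                             follow_up_days = c(min = 60, max = 90),
                             record_completeness = 0.5,
                             hf_effect = c(weight = 0, urine = 0, sbp = 0, dbp = eff),
                             seed = s)
        co <- generate_cohort(cfg)
        fl <- discretize_cohort(co)
        rows <- build_rows(co, fl, 0.05)
        mean(rows$dbp_cat[rows$hf_label == 1] == "abnormal")
      }
      c(lo = rate_at(1), hi = rate_at(3))
    })
  })
  d <- rates["hi", ] - rates["lo", ]
  expect_gt(mean(d), 3 * sd(d) / sqrt(length(d)))
})

test_that("cohorts round-trip through CSV exactly", {
  co <- generate_cohort(test_config(n = 80, seed = 33))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$patients, co$patients)
  expect_equal(back$records, co$records)
})

test_that("an empty cohort writes header-only files and reads back empty", {
  co <- generate_cohort(cohort_config(n_patients = 0, seed = 1))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_identical(length(readLines(file.path(dir, "records.csv"))), 1L)
  back <- read_cohort(dir)
  expect_identical(nrow(back$patients), 0L)
  expect_identical(nrow(back$records), 0L)
})

test_that("corrupt rows are rejected with a row-level diagnostic", {
  co <- generate_cohort(test_config(n = 20, seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  rl <- readLines(file.path(dir, "records.csv"))
  parts <- strsplit(rl[5], ",")[[1]]
  parts[5] <- "40"; parts[6] <- "90"  # sbp <= dbp
  rl[5] <- paste(parts, collapse = ",")
  writeLines(rl, file.path(dir, "records.csv"))
  expect_error(read_cohort(dir), "row 4")
  diag <- validate_inputs(records = file.path(dir, "records.csv"))
  expect_identical(diag$row, 4L)
  expect_match(diag$message, "sbp")
})
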