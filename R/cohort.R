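# Synthetic monitored-cohort generator.
#
# Each patient contributes a profile (sex, age, time on peritoneal dialysis,
# optional heart-failure hospitalization date) and a sparse stream of daily
# vitals records. Within a patient each vital follows
#   value(day) = intercept_i + slope_i * day + e,   e ~ N(0, within-SD),
# the same functional form the downstream least-squares detector assumes.
# Heart-failure cases receive an additive shift (in within-patient SD units)
# on every monitored day inside the progression window, the `hf_window_days`
# days immediately before the hospitalization date.

#' Configuration for the synthetic monitoring cohort
#'
#' Defaults reproduce the structure of the monitored home peritoneal-dialysis
#' cohort the package models: 6635 patients, heart-failure prevalence 0.71%,
#' 61.15% female, age median 46.9 (IQR 44.68-50.59) years, dialysis duration
#' median 1.00 (IQR 0.53-1.64) years, and a progression signal confined to the
#' 15 days before heart-failure hospitalization. Ages and dialysis durations
#' are log-normal, matched to the median/IQR. Heart-failure risk follows a
#' logistic model in age and sex (`hf_log_or`), with the intercept calibrated
#' so the mean risk equals `hf_prevalence`.
#'
#' @param n_patients Number of patients.
#' @param hf_prevalence Probability a patient experiences heart-failure
#'   hospitalization during follow-up.
#' @param follow_up_days Length-2 numeric `c(min, max)`; each patient's
#'   follow-up is drawn uniformly (in whole days) from this range.
#' @param female_fraction Probability a patient is female.
#' @param age_dist,pd_duration_dist Lists with `median` and `iqr` (length-2)
#'   in years; fitted by a two-parameter log-normal.
#' @param baseline_levels Per-vital named list of `c(mean, between_sd,
#'   within_sd)` giving the population mean, between-patient SD of the
#'   personal level, and within-patient day-to-day SD. Units: weight kg,
#'   urine mL/day, sbp/dbp mmHg.
#' @param trend_slope_sd Per-vital SD of the personal linear drift,
#'   units/day.
#' @param hf_effect Per-vital shift applied on progression-window days, in
#'   within-patient SD units.
#' @param bp_noise_cor Within-day correlation between the systolic and
#'   diastolic noise terms (the two pressures are read from the same
#'   measurement, so their day-to-day fluctuations co-move).
#' @param hf_log_or Named vector `c(female=, age=)` of log odds-ratios for
#'   heart-failure risk (age per year, centred at the age median).
#' @param hf_window_days Length of the progression window, days.
#' @param record_completeness Probability that any given follow-up day yields
#'   an uploaded record. Real home-monitoring streams are sparse; the default
#'   (0.10) places on average 1.5 records inside a 15-day assessment window,
#'   which reproduces observed patient-level abnormality rates.
#' @param enrollment_start First possible enrollment date.
#' @param enrollment_span_days Enrollment dates are uniform over this many
#'   days from `enrollment_start`.
#' @param seed Optional integer; when set, generation is a pure function of
#'   the configuration.
#'
#' @return A validated list of class `pdhf_cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 6635,
                          hf_prevalence = 0.0071,
                          follow_up_days = c(min = 150, max = 720),
                          female_fraction = 0.6115,
                          age_dist = list(median = 46.9, iqr = c(44.68, 50.59)),
                          pd_duration_dist = list(median = 1.00, iqr = c(0.53, 1.64)),
                          baseline_levels = list(
                            weight = c(mean = 60,  between_sd = 12,  within_sd = 0.8),
                            urine  = c(mean = 800, between_sd = 400, within_sd = 120),
                            sbp    = c(mean = 135, between_sd = 15,  within_sd = 8),
                            dbp    = c(mean = 85,  between_sd = 10,  within_sd = 6)),
                          trend_slope_sd = c(weight = 0.01, urine = 0.5,
                                             sbp = 0.02, dbp = 0.015),
                          hf_effect = c(weight = 0.5, urine = -0.5,
                                        sbp = 1.2, dbp = 3.0),
                          bp_noise_cor = 0.6,
                          hf_log_or = c(female = log(0.10), age = log(1.17)),
                          hf_window_days = 15,
                          record_completeness = 0.10,
                          enrollment_start = as.Date("2017-01-01"),
                          enrollment_span_days = 1800,
                          seed = NULL) {
  cfg <- list(n_patients = n_patients, hf_prevalence = hf_prevalence,
              follow_up_days = follow_up_days, female_fraction = female_fraction,
              age_dist = age_dist, pd_duration_dist = pd_duration_dist,
              baseline_levels = baseline_levels, trend_slope_sd = trend_slope_sd,
              hf_effect = hf_effect, bp_noise_cor = bp_noise_cor,
              hf_log_or = hf_log_or,
              hf_window_days = hf_window_days,
              record_completeness = record_completeness,
              enrollment_start = as.Date(enrollment_start),
              enrollment_span_days = enrollment_span_days, seed = seed)
  class(cfg) <- "pdhf_cohort_config"
  .check_cohort_config(cfg)
  cfg
}

.check_cohort_config <- function(cfg) {
  .assert(.is_count(cfg$n_patients), "n_patients", "must be a non-negative integer")
  .assert(.is_prob(cfg$hf_prevalence), "hf_prevalence", "must be a probability in [0, 1]")
  .assert(.is_prob(cfg$female_fraction), "female_fraction", "must be a probability in [0, 1]")
  .assert(.is_prob(cfg$record_completeness) && cfg$record_completeness > 0,
          "record_completeness", "must be a probability in (0, 1]")
  fu <- cfg$follow_up_days
  .assert(is.numeric(fu) && length(fu) == 2L && all(fu >= 1) && fu[2] >= fu[1],
          "follow_up_days", "must be c(min, max) with max >= min >= 1")
  .assert(is.numeric(cfg$hf_window_days) && length(cfg$hf_window_days) == 1L &&
            cfg$hf_window_days >= 1,
          "hf_window_days", "must be >= 1")
  for (d in c("age_dist", "pd_duration_dist")) {
    dd <- cfg[[d]]
    .assert(is.list(dd) && is.numeric(dd$median) && dd$median > 0 &&
              length(dd$iqr) == 2L && all(dd$iqr > 0) && dd$iqr[2] > dd$iqr[1],
            d, "needs positive `median` and increasing positive `iqr`")
  }
  .assert(is.list(cfg$baseline_levels) &&
            all(names(.pd_vitals) %in% names(cfg$baseline_levels)),
          "baseline_levels", "must name weight, urine, sbp, dbp")
  for (v in names(.pd_vitals)) {
    bl <- cfg$baseline_levels[[v]]
    .assert(is.numeric(bl) && length(bl) == 3L && all(bl[2:3] >= 0),
            paste0("baseline_levels$", v),
            "must be c(mean, between_sd, within_sd) with SDs >= 0")
  }
  .assert(is.numeric(cfg$trend_slope_sd) &&
            all(names(.pd_vitals) %in% names(cfg$trend_slope_sd)) &&
            all(cfg$trend_slope_sd >= 0),
          "trend_slope_sd", "must be a named non-negative vector over the vitals")
  .assert(is.numeric(cfg$hf_effect) &&
            all(names(.pd_vitals) %in% names(cfg$hf_effect)),
          "hf_effect", "must be a named vector over the vitals")
  .assert(is.numeric(cfg$bp_noise_cor) && cfg$bp_noise_cor >= -1 &&
            cfg$bp_noise_cor <= 1,
          "bp_noise_cor", "must be a correlation in [-1, 1]")
  .assert(is.numeric(cfg$hf_log_or) &&
            all(c("female", "age") %in% names(cfg$hf_log_or)),
          "hf_log_or", "must name `female` and `age`")
  invisible(cfg)
}

.sdlog_from_iqr <- function(median, iqr) {
  # two-parameter log-normal matched to printed median and IQR
  log(iqr[2] / iqr[1]) / (2 * qnorm(0.75))
}

.generate_profiles <- function(cfg) {
  n <- cfg$n_patients
  if (n == 0L) {
    return(data.frame(patient_id = character(), sex = character(),
                      age_years = numeric(), first_dialysis_date = as.Date(character()),
                      pd_duration_years = numeric(), hf_date = as.Date(character()),
                      enrollment_date = as.Date(character()),
                      follow_up_days = integer()))
  }
  sex <- ifelse(runif(n) < cfg$female_fraction, "female", "male")
  age <- round(rlnorm(n, log(cfg$age_dist$median),
                      .sdlog_from_iqr(cfg$age_dist$median, cfg$age_dist$iqr)), 2)
  pd <- round(pmax(rlnorm(n, log(cfg$pd_duration_dist$median),
                          .sdlog_from_iqr(cfg$pd_duration_dist$median,
                                          cfg$pd_duration_dist$iqr)), 0.01), 2)
  fu <- cfg$follow_up_days[[1]] +
    sample.int(cfg$follow_up_days[[2]] - cfg$follow_up_days[[1]] + 1L, n,
               replace = TRUE) - 1L
  enroll <- cfg$enrollment_start + sample.int(cfg$enrollment_span_days, n, replace = TRUE) - 1L

  # logistic heart-failure risk in age and sex, intercept calibrated so that
  # the mean risk equals the target prevalence
  off <- cfg$hf_log_or[["age"]] * (age - cfg$age_dist$median) +
    cfg$hf_log_or[["female"]] * (sex == "female")
  if (cfg$hf_prevalence <= 0) {
    hf <- rep(FALSE, n)
  } else if (cfg$hf_prevalence >= 1) {
    hf <- rep(TRUE, n)
  } else {
    b0 <- uniroot(function(b) mean(plogis(b + off)) - cfg$hf_prevalence,
                  c(-40, 40), tol = 1e-10)$root
    hf <- runif(n) < plogis(b0 + off)
  }
  # hospitalization uniform over the last third of follow-up, so a complete
  # progression window precedes it (follow-up minimum >= 3 * window length
  # is not enforced; the labeller truncates if needed)
  hf_day <- rep(NA_integer_, n)
  if (any(hf)) {
    lo <- pmax(ceiling(2 * fu / 3), cfg$hf_window_days + 1)
    hf_day[hf] <- floor(runif(sum(hf), lo[hf], fu[hf] + 1))
  }
  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    sex = sex,
    age_years = age,
    first_dialysis_date = enroll - round(pd * 365.25),
    pd_duration_years = pd,
    hf_date = enroll + hf_day - 1L,
    enrollment_date = enroll,
    follow_up_days = as.integer(fu),
    stringsAsFactors = FALSE
  )
}

.generate_records <- function(cfg, prof) {
  n <- nrow(prof)
  empty <- data.frame(patient_id = character(), date = as.Date(character()),
                      weight_kg = numeric(), urine_ml = numeric(),
                      sbp_mmhg = numeric(), dbp_mmhg = numeric())
  if (n == 0L) return(empty)
  fu <- prof$follow_up_days
  idx <- rep.int(seq_len(n), fu)
  day <- sequence(fu)
  keep <- runif(length(day)) < cfg$record_completeness
  idx <- idx[keep]; day <- day[keep]
  m <- length(day)
  if (m == 0L) return(empty)

  hf <- !is.na(prof$hf_date)
  hf_day <- as.integer(prof$hf_date - prof$enrollment_date) + 1L
  in_window <- hf[idx] & !is.na(hf_day[idx]) &
    day >= hf_day[idx] - cfg$hf_window_days & day < hf_day[idx]

  # within-day noise: independent for weight/urine; correlated between the
  # two blood pressures (both read from the same measurement of the day's
  # hemodynamic state). Progression-window days carry a shared fluid-overload
  # severity (mean-1 exponential), so one severe day moves every vital at
  # once — the collinear excursion pattern seen in monitored cohorts.
  rho <- cfg$bp_noise_cor
  z_shared <- rnorm(m)
  severity <- in_window * stats::rexp(m)
  vals <- vector("list", length(.pd_vitals))
  names(vals) <- names(.pd_vitals)
  for (v in names(.pd_vitals)) {
    bl <- cfg$baseline_levels[[v]]
    a_i <- rnorm(n, bl[[1]], bl[[2]])
    b_i <- rnorm(n, 0, cfg$trend_slope_sd[[v]])
    noise <- if (v %in% c("sbp", "dbp")) {
      bl[[3]] * (rho * z_shared + sqrt(1 - rho^2) * rnorm(m))
    } else {
      rnorm(m, 0, bl[[3]])
    }
    y <- a_i[idx] + b_i[idx] * (day - 1) + noise +
      severity * cfg$hf_effect[[v]] * bl[[3]]
    vals[[v]] <- y
  }
  # measurement granularity: scales report 0.1 kg, monitors whole mmHg / mL
  weight <- pmax(round(vals$weight, 1), 0.1)
  urine <- pmax(round(vals$urine), 0)
  sbp <- round(vals$sbp)
  dbp <- pmin(round(vals$dbp), sbp - 1)  # physical constraint sbp > dbp
  dbp <- pmax(dbp, 1)
  sbp <- pmax(sbp, dbp + 1)

  data.frame(
    patient_id = prof$patient_id[idx],
    date = prof$enrollment_date[idx] + day - 1L,
    weight_kg = weight, urine_ml = urine,
    sbp_mmhg = sbp, dbp_mmhg = dbp,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic monitoring cohort
#'
#' Draws patient profiles and sparse daily vitals streams according to a
#' [cohort_config()]. Heart-failure cases carry the configured per-vital shift
#' on monitored days inside the progression window (the `hf_window_days` days
#' strictly before the hospitalization date). With a seed the result is a pure
#' function of the configuration.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`. The caller's RNG state
#'   is left untouched.
#' @return An object of class `pdhf_cohort`: a list with data frames
#'   `patients` (one row per patient; `hf_date` is `NA` for non-cases) and
#'   `records` (one row per patient-day with an upload).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 50, seed = 1))
#' summarize_cohort(cohort)
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  .check_cohort_config(config)
  gen <- function() {
    prof <- .generate_profiles(config)
    rec <- .generate_records(config, prof)
    structure(list(patients = prof, records = rec), class = "pdhf_cohort")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Summarize a cohort
#'
#' @param cohort A `pdhf_cohort`.
#' @return List with patient counts, heart-failure count and prevalence (%),
#'   female percentage, median age and dialysis duration, and record count.
#' @export
summarize_cohort <- function(cohort) {
  p <- cohort$patients
  n <- nrow(p)
  n_hf <- sum(!is.na(p$hf_date))
  list(
    n_patients = n,
    n_records = nrow(cohort$records),
    n_hf = n_hf,
    hf_prevalence_pct = if (n > 0) round(100 * n_hf / n, 2) else NA_real_,
    female_pct = if (n > 0) round(100 * mean(p$sex == "female"), 2) else NA_real_,
    median_age_years = if (n > 0) stats::median(p$age_years) else NA_real_,
    median_pd_duration_years = if (n > 0) stats::median(p$pd_duration_years) else NA_real_
  )
}

#' @export
print.pdhf_cohort <- function(x, ...) {
  s <- summarize_cohort(x)
  cat(sprintf(
    "<pdhf_cohort> %d patients, %d records, %d heart-failure cases (%.2f%%)\n",
    s$n_patients, s$n_records, s$n_hf, s$hf_prevalence_pct))
  invisible(x)
}

#' Write / read a cohort as delimited text
#'
#' `write_cohort()` writes `patients.csv` and `records.csv` (ISO-8601 dates,
#' UTF-8) into a directory; `read_cohort()` reads them back, validating every
#' row. The round trip reproduces the cohort exactly.
#'
#' @param cohort A `pdhf_cohort`.
#' @param path Directory to write into (created if needed) / read from.
#' @return `write_cohort()` the path, invisibly; `read_cohort()` a
#'   `pdhf_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  p <- cohort$patients
  p$first_dialysis_date <- format(p$first_dialysis_date)
  p$hf_date <- ifelse(is.na(p$hf_date), "", format(p$hf_date))
  if ("enrollment_date" %in% names(p)) p$enrollment_date <- format(p$enrollment_date)
  r <- cohort$records
  r$date <- format(r$date)
  write.csv(p, file.path(path, "patients.csv"), row.names = FALSE, quote = FALSE)
  write.csv(r, file.path(path, "records.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  pf <- file.path(path, "patients.csv")
  rf <- file.path(path, "records.csv")
  for (f in c(pf, rf)) if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  diag <- validate_inputs(records = rf, patients = pf)
  if (nrow(diag) > 0) {
    stop("invalid cohort files:\n",
         paste(utils::head(sprintf("  %s row %s [%s]: %s", diag$table, diag$row,
                                   diag$column, diag$message), 10L),
               collapse = "\n"),
         if (nrow(diag) > 10) sprintf("\n  ... and %d more", nrow(diag) - 10L),
         call. = FALSE)
  }
  p <- read.csv(pf, stringsAsFactors = FALSE, colClasses = "character")
  r <- read.csv(rf, stringsAsFactors = FALSE, colClasses = "character")
  p$age_years <- as.numeric(p$age_years)
  p$pd_duration_years <- as.numeric(p$pd_duration_years)
  p$first_dialysis_date <- as.Date(p$first_dialysis_date)
  p$hf_date <- as.Date(ifelse(p$hf_date == "", NA, p$hf_date))
  if ("enrollment_date" %in% names(p)) p$enrollment_date <- as.Date(p$enrollment_date)
  if ("follow_up_days" %in% names(p)) p$follow_up_days <- as.integer(p$follow_up_days)
  r$date <- as.Date(r$date)
  r$weight_kg <- as.numeric(r$weight_kg)
  r$urine_ml <- as.numeric(r$urine_ml)
  r$sbp_mmhg <- as.numeric(r$sbp_mmhg)
  r$dbp_mmhg <- as.numeric(r$dbp_mmhg)
  structure(list(patients = p, records = r), class = "pdhf_cohort")
}
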