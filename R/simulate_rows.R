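# Direct simulator for patient-level analysis rows. Used for parameter
# recovery and selection-behavior studies where the full daily-stream
# generator is unnecessary: covariates are drawn marginally and the
# heart-failure label follows a logistic model with known coefficients.

#' Simulate analysis rows from a known logistic model
#'
#' Draws sex, age, dialysis duration and the five normal/abnormal categories
#' independently, then assigns the heart-failure label from a logistic model
#' with the supplied coefficients (sex female, age in years centred at
#' `age_center`, and the abnormal diastolic-pressure category). The remaining
#' categories are pure noise with the given marginal abnormality rates.
#'
#' @param n Number of rows.
#' @param coef Named vector: `intercept`, `female`, `age` (per year),
#'   `dbp_abnormal`, on the log-odds scale.
#' @param female_fraction Probability of female sex.
#' @param age_mean,age_sd Normal age distribution (years).
#' @param age_center Centring constant for the age effect.
#' @param pd_duration_dist Log-normal `median`/`iqr` for dialysis duration.
#' @param p_abnormal Named marginal abnormality probabilities for
#'   `weight`, `urine`, `sbp`, `dbp`, `pp`.
#' @param seed Optional seed.
#' @return Analysis rows shaped like [build_rows()] output, with an attribute
#'   `true_coef`.
#' @export
simulate_analysis_rows <- function(n,
                                   coef = c(intercept = -1.8,
                                            female = log(0.06),
                                            age = log(1.19),
                                            dbp_abnormal = log(38.79)),
                                   female_fraction = 0.6,
                                   age_mean = 47, age_sd = 8,
                                   age_center = 47,
                                   pd_duration_dist = list(median = 1.00,
                                                           iqr = c(0.53, 1.64)),
                                   p_abnormal = c(weight = 0.03, urine = 0.04,
                                                  sbp = 0.04, dbp = 0.05,
                                                  pp = 0.04),
                                   seed = NULL) {
  stopifnot(all(c("intercept", "female", "age", "dbp_abnormal") %in% names(coef)))
  gen <- function() {
    sex <- factor(ifelse(runif(n) < female_fraction, "female", "male"),
                  levels = c("male", "female"))
    age <- rnorm(n, age_mean, age_sd)
    pd <- rlnorm(n, log(pd_duration_dist$median),
                 .sdlog_from_iqr(pd_duration_dist$median, pd_duration_dist$iqr))
    cat_draw <- function(p) factor(ifelse(runif(n) < p, "abnormal", "normal"),
                                   levels = c("normal", "abnormal"))
    dbp_cat <- cat_draw(p_abnormal[["dbp"]])
    lp <- coef[["intercept"]] +
      coef[["female"]] * (sex == "female") +
      coef[["age"]] * (age - age_center) +
      coef[["dbp_abnormal"]] * (dbp_cat == "abnormal")
    rows <- data.frame(
      patient_id = sprintf("S%06d", seq_len(n)),
      sex = sex,
      age = age,
      pd_duration = pd,
      weight_cat = cat_draw(p_abnormal[["weight"]]),
      urine_cat = cat_draw(p_abnormal[["urine"]]),
      sbp_cat = cat_draw(p_abnormal[["sbp"]]),
      dbp_cat = dbp_cat,
      pp_cat = cat_draw(p_abnormal[["pp"]]),
      hf_label = as.integer(runif(n) < plogis(lp)),
      stringsAsFactors = FALSE
    )
    rows
  }
  rows <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  attr(rows, "true_coef") <- coef
  attr(rows, "age_center") <- age_center
  rows
}
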