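# Independent brute-force oracles used to cross-check the package's
# closed-form implementations. Deliberately written with different machinery
# (lm/predict, explicit pair loops, explicit likelihood sums).

# pointwise prediction/confidence band of a simple linear regression,
# via stats::lm + predict
oracle_band <- function(t, y, alpha = 0.05, interval = "prediction") {
  fit <- lm(y ~ t)
  pr <- predict(fit, newdata = data.frame(t = t), interval = interval,
                level = 1 - alpha)
  data.frame(fitted = pr[, "fit"], lower = pr[, "lwr"], upper = pr[, "upr"])
}

# AUC by exhaustive case-control pair counting (ties count 1/2)
oracle_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(s1) * length(s0))
}

# Bernoulli log-likelihood and AIC from predicted probabilities
oracle_loglik <- function(p, y) sum(log(ifelse(y == 1, p, 1 - p)))
oracle_aic <- function(p, y, k) 2 * k - 2 * oracle_loglik(p, y)

# decision-curve net benefit by explicit counting
oracle_net_benefit <- function(scores, labels, pt) {
  n <- length(labels)
  tp <- 0; fp <- 0
  for (i in seq_len(n)) {
    if (scores[i] >= pt) {
      if (labels[i] == 1) tp <- tp + 1 else fp <- fp + 1
    }
  }
  tp / n - (fp / n) * pt / (1 - pt)
}

# one-patient cohort with fully specified record values (constant unless
# overridden); handy for deterministic flagging scenarios
make_test_cohort <- function(dates, dbp = 80, sbp = 160, weight = 60,
                             urine = 800, hf_date = NA, patient_id = "T01",
                             sex = "female", age = 50, pd = 1.2) {
  k <- length(dates)
  rec <- function(x) rep_len(x, k)
  patients <- data.frame(
    patient_id = patient_id, sex = sex, age_years = age,
    first_dialysis_date = min(dates) - 400,
    pd_duration_years = pd,
    hf_date = as.Date(hf_date),
    stringsAsFactors = FALSE)
  records <- data.frame(
    patient_id = patient_id, date = dates,
    weight_kg = rec(weight), urine_ml = rec(urine),
    sbp_mmhg = rec(sbp), dbp_mmhg = rec(dbp),
    stringsAsFactors = FALSE)
  structure(list(patients = patients, records = records),
            class = "pdhf_cohort")
}

# a small, quick default configuration for tests that need a whole cohort
test_config <- function(n = 300, seed = 1, ...) {
  cohort_config(n_patients = n, hf_prevalence = 0.15,
                follow_up_days = c(min = 90, max = 150),
                record_completeness = 0.5, seed = seed, ...)
}
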