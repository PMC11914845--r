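# Personalized least-squares baselines and discrete-point flagging.
#
# Each patient's vital is regressed on days since their first record. An
# observation is a "discrete point" when it is incompatible with the patient's
# own fitted trend at level alpha. Two rules are available:
#
#   * "studentized" (default): the externally studentized (leave-one-out)
#     residual exceeds t(1 - alpha/2, n - 3). Under the trend + Gaussian-noise
#     model the per-point flag rate is exactly alpha.
#   * "band": the raw observation lies strictly outside the two-sided
#     1 - alpha prediction band of the fit that included it. Slightly
#     conservative for points used in the fit (the band variance 1 + h_ii
#     overstates the residual variance 1 - h_ii).
#
# Both rules are monotone in alpha, so flags at alpha = .01 are a subset of
# flags at alpha = .05.

#' Extract one patient's series from a cohort
#'
#' @param cohort A `pdhf_cohort`.
#' @param patient_id Patient identifier.
#' @return Object of class `pdhf_series`: list with `profile` (one-row data
#'   frame) and `records` (time-ordered daily records).
#' @export
patient_series <- function(cohort, patient_id) {
  i <- match(patient_id, cohort$patients$patient_id)
  if (is.na(i)) stop("unknown patient_id: ", patient_id, call. = FALSE)
  rec <- cohort$records[cohort$records$patient_id == patient_id, , drop = FALSE]
  rec <- rec[order(rec$date), , drop = FALSE]
  structure(list(profile = cohort$patients[i, , drop = FALSE],
                 records = rec),
            class = "pdhf_series")
}

# observed values of a (possibly derived) variable; pulse pressure is always
# derived as sbp - dbp, never stored
.series_values <- function(records, variable) {
  if (variable == "pulse_pressure")
    return(records$sbp_mmhg - records$dbp_mmhg)
  col <- .pd_vitals[[variable]]
  if (is.null(col)) stop("unknown variable: ", variable, call. = FALSE)
  records[[col]]
}

#' Fit a patient's least-squares baseline for one vital
#'
#' Ordinary least squares of the vital against days since the patient's first
#' record, with the pointwise two-sided band at level `1 - alpha` evaluated at
#' every observed date. The default band is the prediction interval for a new
#' observation; `band = "confidence"` gives the narrower mean-response band.
#'
#' @param series A `pdhf_series` or a records data frame.
#' @param variable One of `"weight"`, `"urine"`, `"sbp"`, `"dbp"`,
#'   `"pulse_pressure"`.
#' @param alpha Band level (e.g. 0.05 for the 95% band).
#' @param min_obs Minimum number of observations; fewer raises a condition of
#'   class `pdhf_insufficient_data`.
#' @param band `"prediction"` (default) or `"confidence"`.
#' @return Object of class `baseline_fit` with elements `intercept`, `slope`
#'   (units/day), `residual_sd`, `n_obs`, `alpha`, a `band` data frame
#'   (`date`, `observed`, `fitted`, `lower`, `upper`), leverage and
#'   studentized residuals.
#' @export
fit_baseline <- function(series, variable, alpha = 0.05, min_obs = 10,
                         band = c("prediction", "confidence")) {
  band <- match.arg(band)
  rec <- if (inherits(series, "pdhf_series")) series$records else series
  pid <- if (inherits(series, "pdhf_series")) series$profile$patient_id else
    rec$patient_id[1] %||% NA_character_
  y <- .series_values(rec, variable)
  ok <- !is.na(y)
  y <- y[ok]
  dates <- rec$date[ok]
  n <- length(y)
  min_obs <- max(min_obs, 4L)  # studentized residuals need n - 3 >= 1
  if (n < min_obs) {
    stop(structure(class = c("pdhf_insufficient_data", "error", "condition"),
                   list(message = sprintf(
                     "patient %s, variable %s: %d observations < min_obs = %d",
                     pid, variable, n, min_obs), call = NULL)))
  }
  t <- as.numeric(dates - dates[1])
  tbar <- mean(t)
  dtc <- t - tbar
  sxx <- sum(dtc^2)
  slope <- sum(dtc * y) / sxx
  intercept <- mean(y) - slope * tbar
  fit <- intercept + slope * t
  e <- y - fit
  rss <- sum(e^2)
  s2 <- rss / (n - 2)
  h <- 1 / n + dtc^2 / sxx
  scale2 <- if (band == "prediction") 1 + h else h
  half <- qt(1 - alpha / 2, n - 2) * sqrt(s2 * scale2)

  # externally studentized residuals (exact t(n-3) null distribution)
  s2i <- (rss - e^2 / (1 - h)) / (n - 3)
  s2i[s2i < 0] <- 0
  den <- sqrt(s2i * (1 - h))
  tol <- 1e-10 * (mean(abs(y)) + 1)
  rstud <- ifelse(den > tol, e / den, ifelse(abs(e) > tol, sign(e) * Inf, 0))

  structure(list(
    patient_id = pid, variable = variable, alpha = alpha,
    intercept = intercept, slope = slope,
    residual_sd = sqrt(s2), n_obs = n, band_type = band,
    leverage = h, rstudent = rstud,
    band = data.frame(date = dates, observed = y, fitted = fit,
                      lower = fit - half, upper = fit + half)
  ), class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf(
    "<baseline_fit> %s / %s: n = %d, intercept = %.3f, slope = %.5f/day, residual SD = %.3f (alpha = %.2f, %s band)\n",
    x$patient_id, x$variable, x$n_obs, x$intercept, x$slope, x$residual_sd,
    x$alpha, x$band_type))
  invisible(x)
}

#' Dates of discrete points for one fitted baseline
#'
#' @param fit A [fit_baseline()] result.
#' @param method `"studentized"` (leave-one-out studentized residual against
#'   `t(n - 3)`; calibrated so the per-point rate under the model equals
#'   `alpha`) or `"band"` (observation strictly outside the fit's band;
#'   boundary points are not discrete).
#' @return `Date` vector (possibly empty) of flagged observation dates.
#' @export
flag_discrete_points <- function(fit, method = c("studentized", "band")) {
  method <- match.arg(method)
  if (method == "band") {
    out <- fit$band$observed < fit$band$lower | fit$band$observed > fit$band$upper
  } else {
    crit <- qt(1 - fit$alpha / 2, fit$n_obs - 3)
    out <- abs(fit$rstudent) > crit
  }
  fit$band$date[out]
}

# assessment window for a profile: progression window for cases, the trailing
# window of follow-up for everyone else (follow-up end from the profile when
# known, otherwise the last observed record)
.assessment_window <- function(profile, last_record_date, window_days = 15) {
  if (!is.na(profile$hf_date)) {
    return(c(start = profile$hf_date - window_days, end = profile$hf_date - 1))
  }
  end <- if (!is.null(profile$enrollment_date) &&
             !is.null(profile$follow_up_days) &&
             !is.na(profile$enrollment_date) && !is.na(profile$follow_up_days)) {
    profile$enrollment_date + profile$follow_up_days - 1
  } else {
    last_record_date
  }
  if (is.na(end)) return(c(start = as.Date(NA), end = as.Date(NA)))
  c(start = end - window_days + 1, end = end)
}

#' Convert one patient's vitals into normal/abnormal categories
#'
#' Fits every vital (weight, urine, systolic/diastolic pressure, derived pulse
#' pressure), flags discrete points, and assigns the category `abnormal` to a
#' variable/alpha pair when at least one discrete point falls inside the
#' assessment window. Cases are assessed over the progression window
#' `[hf_date - window_days, hf_date)`; other patients over their trailing
#' `window_days` of follow-up. Patients with fewer than `min_obs`
#' observations for a variable default to `normal` and are marked
#' `insufficient`.
#'
#' @param series A `pdhf_series`.
#' @param window Optional `c(start, end)` `Date` pair overriding the default
#'   assessment window. A window that does not intersect the observed dates
#'   raises a warning of class `pdhf_empty_window`.
#' @param alphas Numeric vector of band levels.
#' @param window_days Assessment-window length in days.
#' @param min_obs Minimum observations per variable.
#' @inheritParams flag_discrete_points
#' @inheritParams fit_baseline
#' @return Data frame with one row per variable x alpha: `patient_id`,
#'   `variable`, `alpha`, `category`, `n_discrete_points`, `dates`
#'   (semicolon-joined), `n_obs`, `insufficient`.
#' @export
discretize_patient <- function(series, window = NULL, alphas = c(0.05, 0.01),
                               window_days = 15, min_obs = 10,
                               method = c("studentized", "band"),
                               band = c("prediction", "confidence")) {
  method <- match.arg(method)
  band <- match.arg(band)
  rec <- series$records
  last_date <- if (nrow(rec) > 0) max(rec$date) else as.Date(NA)
  if (is.null(window)) {
    window <- .assessment_window(series$profile, last_date, window_days)
  }
  if (nrow(rec) > 0 && !is.na(window[1]) &&
      (window[2] < min(rec$date) || window[1] > max(rec$date))) {
    warning(structure(class = c("pdhf_empty_window", "warning", "condition"),
                      list(message = sprintf(
                        "patient %s: assessment window [%s, %s] outside observed range [%s, %s]",
                        series$profile$patient_id, window[1], window[2],
                        min(rec$date), max(rec$date)), call = NULL)))
  }
  out <- vector("list", length(.pd_flag_vars) * length(alphas))
  k <- 0L
  for (v in .pd_flag_vars) {
    fits <- lapply(alphas, function(a) {
      tryCatch(fit_baseline(series, v, alpha = a, min_obs = min_obs, band = band),
               pdhf_insufficient_data = function(e) NULL)
    })
    for (j in seq_along(alphas)) {
      k <- k + 1L
      f <- fits[[j]]
      if (is.null(f)) {
        out[[k]] <- data.frame(patient_id = series$profile$patient_id,
                               variable = v, alpha = alphas[j],
                               category = "normal", n_discrete_points = 0L,
                               dates = "", n_obs = nrow(rec),
                               insufficient = TRUE, stringsAsFactors = FALSE)
        next
      }
      dts <- flag_discrete_points(f, method = method)
      if (!is.na(window[1])) {
        dts <- dts[dts >= window[1] & dts <= window[2]]
      } else {
        dts <- dts[0]
      }
      out[[k]] <- data.frame(patient_id = series$profile$patient_id,
                             variable = v, alpha = alphas[j],
                             category = if (length(dts) > 0) "abnormal" else "normal",
                             n_discrete_points = length(dts),
                             dates = paste(format(dts), collapse = ";"),
                             n_obs = f$n_obs, insufficient = FALSE,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Flag every patient in a cohort
#'
#' Vectorized cohort-level version of [discretize_patient()]: one least-squares
#' baseline per patient x variable, discrete points per alpha, and the
#' patient-level normal/abnormal category from the assessment window.
#'
#' @param cohort A `pdhf_cohort`.
#' @param window `"auto"` (progression window for cases, trailing window for
#'   controls) or `"all"` (whole follow-up; used for calibration studies).
#' @inheritParams discretize_patient
#' @return Data frame as in [discretize_patient()], one row per
#'   patient x variable x alpha, covering every patient in the cohort.
#' @export
discretize_cohort <- function(cohort, alphas = c(0.05, 0.01), window_days = 15,
                              min_obs = 10, method = c("studentized", "band"),
                              band = c("prediction", "confidence"),
                              window = c("auto", "all")) {
  method <- match.arg(method)
  band <- match.arg(band)
  window <- match.arg(window)
  stopifnot(length(alphas) >= 1, all(alphas > 0 & alphas < 1))

  rec <- as.data.table(cohort$records)
  pats <- as.data.table(cohort$patients)[, .(patient_id, hf_date)]

  grid <- CJ(patient_id = cohort$patients$patient_id,
             variable = .pd_flag_vars, alpha = alphas, sorted = FALSE)

  if (nrow(rec) == 0L) {
    res <- grid[, .(patient_id, variable, alpha, category = "normal",
                    n_discrete_points = 0L, dates = "", n_obs = 0L,
                    insufficient = TRUE)]
    return(as.data.frame(res))
  }

  setkey(rec, patient_id, date)
  rec[, pulse_pressure := sbp_mmhg - dbp_mmhg]
  long <- melt(rec,
               id.vars = c("patient_id", "date"),
               measure.vars = c(unname(.pd_vitals), "pulse_pressure"),
               variable.name = "variable", value.name = "y",
               variable.factor = FALSE)
  map <- c(stats::setNames(names(.pd_vitals), unname(.pd_vitals)),
           pulse_pressure = "pulse_pressure")
  long[, variable := map[variable]]
  long <- long[!is.na(y)]
  setkey(long, patient_id, variable, date)

  # closed-form simple linear regression per patient x variable through
  # grouped sufficient statistics, then fully vectorized per-row leverage /
  # residual / studentization — no per-group R evaluation
  long[, g := .GRP, by = .(patient_id, variable)]
  g <- long$g
  G <- g[length(g)]
  first_of_group <- which(!duplicated(g))
  tnum <- as.numeric(long$date)
  tnum <- tnum - tnum[first_of_group][g]      # days since group's first record
  yv <- long$y
  ng <- tabulate(g, G)
  st <- rowsum(tnum, g, reorder = FALSE)[, 1]
  sy <- rowsum(yv, g, reorder = FALSE)[, 1]
  stt <- rowsum(tnum * tnum, g, reorder = FALSE)[, 1]
  sty <- rowsum(tnum * yv, g, reorder = FALSE)[, 1]
  syy <- rowsum(yv * yv, g, reorder = FALSE)[, 1]
  say <- rowsum(abs(yv), g, reorder = FALSE)[, 1]
  tb <- st / ng
  yb <- sy / ng
  sxx <- pmax(stt - ng * tb^2, 0)
  slope <- ifelse(sxx > 0, (sty - ng * tb * yb) / sxx, 0)
  rss <- pmax(syy - ng * yb^2 - slope^2 * sxx, 0)
  # sums-based RSS cancels catastrophically only when the fit is essentially
  # exact; snap those to zero
  rss[rss < 1e-18 * pmax(syy, 1)] <- 0

  e <- yv - (yb[g] - slope[g] * tb[g]) - slope[g] * tnum
  h <- 1 / ng[g] + (tnum - tb[g])^2 / ifelse(sxx[g] > 0, sxx[g], Inf)
  tol <- 1e-7 * (say[g] / ng[g] + 1)
  pred_band <- band == "prediction"
  if (method == "band") {
    den <- sqrt(pmax(rss[g] / (ng[g] - 2), 0) * (if (pred_band) 1 + h else h))
    dff <- ng - 2L
  } else {
    den <- sqrt(pmax((rss[g] - e^2 / (1 - h)) / (ng[g] - 3), 0) * (1 - h))
    dff <- ng - 3L
  }
  score <- ifelse(den > tol, abs(e) / den, ifelse(abs(e) > tol, Inf, 0))
  score[ng[g] < min_obs] <- NA_real_

  # per-patient assessment windows; controls are assessed over the trailing
  # window of follow-up (follow-up end when the profile records it,
  # otherwise the last observed record)
  wins <- rec[, .(last_date = max(date)), by = patient_id]
  wins <- merge(wins, pats, by = "patient_id", all.x = TRUE)
  if (window == "all") {
    wins[, `:=`(win_start = as.Date("0001-01-01"), win_end = as.Date("9999-12-31"))]
  } else {
    wins[, fu_end := last_date]
    pp <- cohort$patients
    if (all(c("enrollment_date", "follow_up_days") %in% names(pp))) {
      fu <- as.data.table(pp)[, .(patient_id,
                                  fu_end2 = enrollment_date + follow_up_days - 1L)]
      wins <- merge(wins, fu, by = "patient_id", all.x = TRUE)
      wins[!is.na(fu_end2), fu_end := fu_end2]
      wins[, fu_end2 := NULL]
    }
    wins[, win_start := fifelse(is.na(hf_date),
                                fu_end - window_days + 1L,
                                hf_date - window_days)]
    wins[, win_end := fifelse(is.na(hf_date), fu_end, hf_date - 1L)]
  }
  wi <- match(long$patient_id, wins$patient_id)
  in_window <- long$date >= wins$win_start[wi] & long$date <= wins$win_end[wi]

  gmap <- data.table(g = seq_len(G),
                     patient_id = long$patient_id[first_of_group],
                     variable = long$variable[first_of_group],
                     n_obs = as.integer(ng))
  pieces <- lapply(alphas, function(a) {
    # t quantiles over the few distinct residual dfs, not per row
    crit_g <- qt(1 - a / 2, pmax(dff, 1))   # per group
    fl <- !is.na(score) & score > crit_g[g] & in_window
    ndp <- tabulate(g[fl], G)
    agg <- copy(gmap)
    agg[, n_discrete_points := ndp]
    agg[, dates := ""]
    if (any(fl)) {
      dd <- vapply(split(format(long$date[fl]), g[fl]),
                   paste, character(1), collapse = ";")
      agg[as.integer(names(dd)), dates := unname(dd)]
    }
    agg[, alpha := a]
    agg[, g := NULL]
    agg
  })
  res <- rbindlist(pieces, use.names = TRUE)
  res <- merge(grid, res, by = c("patient_id", "variable", "alpha"),
               all.x = TRUE, sort = FALSE)
  res[is.na(n_obs), `:=`(n_obs = 0L, n_discrete_points = 0L, dates = "")]
  res[, insufficient := n_obs < min_obs]
  res[, category := fifelse(n_discrete_points > 0, "abnormal", "normal")]
  setcolorder(res, c("patient_id", "variable", "alpha", "category",
                     "n_discrete_points", "dates", "n_obs", "insufficient"))
  setorder(res, patient_id, variable, -alpha)
  as.data.frame(res)
}
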