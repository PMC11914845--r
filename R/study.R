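# Study construction: progression-window labelling, patient-level analysis
# rows, ratio-controlled case-control sampling, and the train/validation split.

#' Heart-failure progression window for a patient
#'
#' For a patient with a heart-failure hospitalization date the progression
#' window is the `window_days` days strictly before hospitalization:
#' `[hf_date - window_days, hf_date)`, closed at the lower bound. Records in
#' this window are treated as related to the developing event.
#'
#' @param profile One-row patient profile (needs `hf_date`).
#' @param window_days Window length in days.
#' @param first_record_date Optional first monitored date; when the window
#'   starts before it, a warning is raised and the window is truncated.
#' @return `c(start, end)` as `Date` (end = last day inside the window), or
#'   `NULL` for patients without a hospitalization date.
#' @examples
#' prof <- data.frame(patient_id = "P1", hf_date = as.Date("2020-03-20"))
#' label_hf_window(prof)  # 2020-03-05 .. 2020-03-19
#' @export
label_hf_window <- function(profile, window_days = 15,
                            first_record_date = NULL) {
  hf <- profile$hf_date
  if (is.null(hf) || is.na(hf)) return(NULL)
  start <- hf - window_days
  end <- hf - 1
  if (!is.null(first_record_date) && !is.na(first_record_date) &&
      start < first_record_date) {
    warning(sprintf(
      "patient %s: progression window starts %s, before first record %s; truncated",
      profile$patient_id, format(start), format(first_record_date)),
      call. = FALSE)
    start <- first_record_date
  }
  c(start = start, end = end)
}

#' Assemble model-ready analysis rows
#'
#' One row per patient: profile covariates plus the five normal/abnormal
#' categories at a single alpha criterion, and the heart-failure label
#' (1 if and only if a hospitalization date is present).
#'
#' @param cohort A `pdhf_cohort`.
#' @param flags Output of [discretize_cohort()].
#' @param alpha_criterion Which alpha's categories to use (must be present in
#'   `flags`).
#' @return Data frame with columns `patient_id`, `sex`, `age`, `pd_duration`,
#'   `weight_cat`, `urine_cat`, `sbp_cat`, `dbp_cat`, `pp_cat` (factors with
#'   levels normal/abnormal) and `hf_label`; attribute `alpha_criterion`.
#' @export
build_rows <- function(cohort, flags, alpha_criterion = 0.05) {
  fl <- flags[abs(flags$alpha - alpha_criterion) < 1e-12, , drop = FALSE]
  if (nrow(fl) == 0) {
    stop("no flags at alpha criterion ", alpha_criterion, call. = FALSE)
  }
  p <- cohort$patients
  missing <- setdiff(p$patient_id, unique(fl$patient_id))
  if (length(missing) > 0) {
    stop("flags missing for patients: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10) sprintf(" ... and %d more", length(missing) - 10L),
         call. = FALSE)
  }
  wide <- data.table::dcast(as.data.table(fl), patient_id ~ variable,
                            value.var = "category")
  cols <- c(weight = "weight_cat", urine = "urine_cat", sbp = "sbp_cat",
            dbp = "dbp_cat", pulse_pressure = "pp_cat")
  setnames(wide, names(cols), unname(cols))
  rows <- merge(as.data.table(p)[, .(patient_id, sex, age = age_years,
                                     pd_duration = pd_duration_years,
                                     hf_label = as.integer(!is.na(hf_date)))],
                wide, by = "patient_id", sort = TRUE)
  rows <- as.data.frame(rows)
  rows$sex <- factor(rows$sex, levels = c("male", "female"))
  for (cc in cols) rows[[cc]] <- factor(rows[[cc]], levels = c("normal", "abnormal"))
  rows <- rows[, c("patient_id", "sex", "age", "pd_duration",
                   unname(cols), "hf_label")]
  attr(rows, "alpha_criterion") <- alpha_criterion
  rows
}

#' Draw the ratio-controlled case-control dataset
#'
#' Keeps every heart-failure case and draws `ratio` controls per case,
#' uniformly without replacement from the non-case rows.
#'
#' @param rows Analysis rows ([build_rows()]).
#' @param ratio Controls per case (1:ratio design).
#' @param seed Optional seed; the draw is deterministic given the seed.
#' @return The sampled rows (cases first, then controls in patient-id order),
#'   with attributes `ratio` and `alpha_criterion`.
#' @export
sample_case_control <- function(rows, ratio = 6, seed = NULL) {
  stopifnot(.is_count(ratio), ratio >= 1)
  cases <- rows[rows$hf_label == 1, , drop = FALSE]
  pool <- rows[rows$hf_label == 0, , drop = FALSE]
  n_need <- ratio * nrow(cases)
  if (nrow(cases) == 0) stop("no cases in `rows`", call. = FALSE)
  if (nrow(pool) < n_need) {
    stop(sprintf(
      "not enough controls: need %d (= %d cases x ratio %d) but only %d available",
      n_need, nrow(cases), ratio, nrow(pool)), call. = FALSE)
  }
  pick <- function() sort(sample.int(nrow(pool), n_need))
  idx <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  out <- rbind(cases, pool[idx, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "ratio") <- ratio
  attr(out, "alpha_criterion") <- attr(rows, "alpha_criterion")
  out
}

#' Split a study dataset into training and validation sets
#'
#' Random split stratified by the heart-failure label so both classes appear
#' in validation; per stratum the training size is `round(train_frac * n)`,
#' kept within `[1, n - 1]`. Strata with fewer than 2 members go entirely to
#' training with a warning.
#'
#' @param rows Analysis rows (typically from [sample_case_control()]).
#' @param train_frac Training fraction, in (0, 1).
#' @param seed Optional seed.
#' @return `rows` with an added `split` column (`"train"`/`"validation"`).
#' @export
split_train_validation <- function(rows, train_frac = 0.8, seed = NULL) {
  stopifnot(is.numeric(train_frac), length(train_frac) == 1L,
            train_frac > 0, train_frac < 1)
  assign_split <- function() {
    split <- character(nrow(rows))
    for (lab in unique(rows$hf_label)) {
      idx <- which(rows$hf_label == lab)
      n <- length(idx)
      if (n < 2) {
        warning(sprintf("stratum hf_label=%s has %d member(s); assigned to training",
                        lab, n), call. = FALSE)
        split[idx] <- "train"
        next
      }
      n_tr <- min(max(round(train_frac * n), 1L), n - 1L)
      tr <- sample(idx, n_tr)
      split[tr] <- "train"
      split[setdiff(idx, tr)] <- "validation"
    }
    split
  }
  rows$split <- if (is.null(seed)) assign_split() else
    withr::with_seed(seed, assign_split())
  rows
}
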