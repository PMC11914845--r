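# Pipeline orchestration: one reproducible run from simulation (or loaded
# files) through flagging, study construction, model fitting, validation and
# the ratio sensitivity analysis, with plain-text artifacts and a manifest.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] describing the simulated cohort.
#' @param alphas Alpha criteria for discretization (both are consumed by the
#'   four-model fit).
#' @param ratio Main case:control ratio (1:ratio design).
#' @param ratios_sensitivity Additional ratios for the sensitivity analysis.
#' @param train_frac Training fraction of the study dataset.
#' @param threshold Classification threshold policy (see [evaluate_model()]).
#' @param alpha_stay Backward-elimination stay threshold.
#' @param window_days Assessment/progression window length, days.
#' @param min_obs Minimum observations per patient-variable baseline.
#' @param flag_method Discrete-point rule (see [discretize_cohort()]).
#' @param seeds Named list with independent integer seeds `simulate`,
#'   `sample`, `split`.
#' @return List of class `pdhf_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            alphas = c(0.05, 0.01),
                            ratio = 6,
                            ratios_sensitivity = c(4, 10),
                            train_frac = 0.8,
                            threshold = "youden",
                            alpha_stay = 0.05,
                            window_days = 15,
                            min_obs = 10,
                            flag_method = "studentized",
                            seeds = list(simulate = 101L, sample = 202L,
                                         split = 303L)) {
  .check_cohort_config(cohort)
  .assert(all(c(0.05, 0.01) %in% alphas), "alphas", "must include 0.05 and 0.01")
  .assert(.is_count(ratio) && ratio >= 1, "ratio", "must be a positive integer")
  .assert(is.numeric(train_frac) && train_frac > 0 && train_frac < 1,
          "train_frac", "must be in (0, 1)")
  .assert(is.list(seeds) && all(c("simulate", "sample", "split") %in% names(seeds)),
          "seeds", "must name simulate, sample, split")
  structure(list(cohort = cohort, alphas = alphas, ratio = ratio,
                 ratios_sensitivity = ratios_sensitivity,
                 train_frac = train_frac, threshold = threshold,
                 alpha_stay = alpha_stay, window_days = window_days,
                 min_obs = min_obs, flag_method = flag_method, seeds = seeds),
            class = "pdhf_pipeline_config")
}

.config_json <- function(config) {
  strip <- function(x) {
    if (inherits(x, "Date")) return(format(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> flag -> build -> sample -> split -> fit -> select ->
#' evaluate -> sensitivity, writing every artifact as plain text (CSV/JSON)
#' into `output_dir` together with a manifest capturing the configuration,
#' seeds, versions and artifact checksums. Identical configurations produce
#' byte-identical artifacts and manifests. On stage failure the partial
#' artifacts are retained next to a `FAILED` marker and the error is
#' re-raised.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for artifacts (created if needed).
#' @param cohort Optional pre-built `pdhf_cohort` (e.g. from
#'   [read_cohort()]); when supplied the simulation stage is skipped.
#' @return Invisibly, a list with the cohort summary, flags, study rows,
#'   models, the selected model, the validation report, the sensitivity
#'   results and artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir,
                         cohort = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  run <- function() {
    message("[pdhf] simulating cohort")
    if (is.null(cohort)) {
      cohort <- generate_cohort(config$cohort, seed = config$seeds$simulate)
    }
    write_cohort(cohort, output_dir)

    message("[pdhf] fitting personal baselines and flagging discrete points")
    flags <- discretize_cohort(cohort, alphas = config$alphas,
                               window_days = config$window_days,
                               min_obs = config$min_obs,
                               method = config$flag_method)
    write.csv(flags, file.path(output_dir, "flags.csv"), row.names = FALSE)

    message("[pdhf] building study dataset (ratio 1:", config$ratio, ")")
    main <- sensitivity_analysis(
      cohort, flags, ratios = config$ratio,
      seed_sample = config$seeds$sample, seed_split = config$seeds$split,
      train_frac = config$train_frac, alpha_stay = config$alpha_stay,
      threshold = config$threshold)[[1]]
    if (!is.null(main$error)) stop(main$error, call. = FALSE)

    # persist the study dataset: both criteria side by side plus the split
    rows05 <- build_rows(cohort, flags, 0.05)
    rows99 <- build_rows(cohort, flags, 0.01)
    samp99 <- sample_case_control(rows99, ratio = config$ratio,
                                  seed = config$seeds$sample + config$ratio)
    samp99 <- split_train_validation(samp99, train_frac = config$train_frac,
                                     seed = config$seeds$split + config$ratio)
    samp05 <- rows05[match(samp99$patient_id, rows05$patient_id), , drop = FALSE]
    ds <- samp99
    names(ds) <- sub("_cat$", "_cat_99", names(ds))
    for (cc in grep("_cat$", names(samp05), value = TRUE)) {
      ds[[sub("_cat$", "_cat_95", cc)]] <- samp05[[cc]]
    }
    write.csv(ds, file.path(output_dir, "dataset.csv"), row.names = FALSE)

    message("[pdhf] selected model ", main$model_id, " (",
            paste(main$retained, collapse = " + "), ")")
    models_json <- lapply(main$models, function(m) {
      list(id = m$spec$id, alpha_criterion = m$spec$alpha_criterion,
           selection = m$spec$selection, variables = m$variables,
           coefficients = m$coef, loglik = m$loglik, aic = m$aic,
           training_auc = m$training$auc, penalized = m$penalized)
    })
    jsonlite::write_json(models_json, file.path(output_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")

    rep <- main$report
    report_json <- list(
      model_id = main$model_id, retained = main$retained,
      threshold = rep$threshold, threshold_policy = rep$threshold_policy,
      counts = list(tp = rep$tp, fp = rep$fp, fn = rep$fn, tn = rep$tn),
      sensitivity = rep$sensitivity, specificity = rep$specificity,
      accuracy = rep$accuracy, youden = rep$youden,
      auc = rep$auc, auc_ci = as.list(rep$auc_ci),
      n_validation = rep$n, n_validation_cases = rep$n_cases)
    jsonlite::write_json(report_json, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(rep$roc, file.path(output_dir, "roc.csv"), row.names = FALSE)
    write.csv(rep$decision_curve, file.path(output_dir, "dca.csv"),
              row.names = FALSE)

    sens <- NULL
    if (length(config$ratios_sensitivity) > 0) {
      message("[pdhf] sensitivity analysis, ratios ",
              paste(config$ratios_sensitivity, collapse = ", "))
      sens <- sensitivity_analysis(
        cohort, flags, ratios = config$ratios_sensitivity,
        seed_sample = config$seeds$sample, seed_split = config$seeds$split,
        train_frac = config$train_frac, alpha_stay = config$alpha_stay,
        threshold = config$threshold)
      sens_json <- lapply(sens, function(s) {
        if (!is.null(s$error)) return(list(ratio = s$ratio, error = s$error))
        list(ratio = s$ratio, n_rows = s$n_rows, model_id = s$model_id,
             retained = s$retained, training_auc = s$training_auc,
             auc = s$auc, auc_ci = as.list(s$auc_ci), youden = s$youden)
      })
      jsonlite::write_json(sens_json, file.path(output_dir, "sensitivity.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    cfg_json <- .config_json(config)
    cfg_path <- file.path(output_dir, "config.json")
    writeLines(cfg_json, cfg_path)
    artifacts <- c("patients.csv", "records.csv", "flags.csv", "dataset.csv",
                   "models.json", "report.json", "roc.csv", "dca.csv",
                   if (!is.null(sens)) "sensitivity.json", "config.json")
    manifest <- list(
      package = "pdhf",
      package_version = as.character(utils::packageVersion("pdhf")),
      r_version = R.version.string,
      seeds = config$seeds,
      config_md5 = unname(tools::md5sum(cfg_path)),
      artifacts = lapply(stats::setNames(artifacts, artifacts), function(a) {
        unname(tools::md5sum(file.path(output_dir, a)))
      })
    )
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(cohort_summary = summarize_cohort(cohort), flags = flags,
                   dataset = ds, models = main$models, optimal = main,
                   report = rep, sensitivity = sens,
                   output_dir = output_dir))
  }
  tryCatch(run(), error = function(e) {
    writeLines(conditionMessage(e), file.path(output_dir, "FAILED"))
    stop(e)
  })
}

#' Validate monitoring input files
#'
#' Schema, date-parse and invariant checks for `records.csv` /
#' `patients.csv`, returning row-level diagnostics instead of failing.
#'
#' @param records,patients Paths to CSV files or data frames. Either may be
#'   `NULL` to skip.
#' @return Data frame with columns `table`, `row`, `column`, `message`;
#'   zero rows when the inputs are clean. Row numbers count data rows
#'   (header excluded).
#' @export
validate_inputs <- function(records = NULL, patients = NULL) {
  diags <- list()
  note <- function(table, row, column, message) {
    diags[[length(diags) + 1L]] <<- data.frame(
      table = table, row = row, column = column, message = message,
      stringsAsFactors = FALSE)
  }
  load <- function(x, name) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
      read.csv(x, stringsAsFactors = FALSE, colClasses = "character")
    } else as.data.frame(x)
  }
  chk_date <- function(tab, df, col) {
    v <- as.character(df[[col]])
    blank <- is.na(v) | v == ""
    ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", v) & !is.na(as.Date(v, format = "%Y-%m-%d"))
    bad <- which(!blank & !ok)
    for (i in bad) note(tab, i, col, sprintf("not an ISO-8601 date: '%s'", v[i]))
    invisible(bad)
  }
  chk_num <- function(tab, df, col) {
    v <- suppressWarnings(as.numeric(as.character(df[[col]])))
    bad <- which(is.na(v) & !(is.na(df[[col]]) | df[[col]] == ""))
    for (i in bad) note(tab, i, col, sprintf("not numeric: '%s'", df[[col]][i]))
    v
  }

  if (!is.null(records)) {
    r <- load(records, "records")
    need <- c("patient_id", "date", "weight_kg", "urine_ml", "sbp_mmhg", "dbp_mmhg")
    miss <- setdiff(need, names(r))
    if (length(miss) > 0) {
      note("records", NA, paste(miss, collapse = ","), "missing required column(s)")
    } else {
      chk_date("records", r, "date")
      w <- chk_num("records", r, "weight_kg")
      u <- chk_num("records", r, "urine_ml")
      s <- chk_num("records", r, "sbp_mmhg")
      d <- chk_num("records", r, "dbp_mmhg")
      for (i in which(!is.na(w) & w <= 0)) note("records", i, "weight_kg", "weight must be > 0")
      for (i in which(!is.na(u) & u < 0)) note("records", i, "urine_ml", "urine volume must be >= 0")
      for (i in which(!is.na(d) & d <= 0)) note("records", i, "dbp_mmhg", "dbp must be > 0")
      for (i in which(!is.na(s) & !is.na(d) & s <= d)) {
        note("records", i, "sbp_mmhg", sprintf("sbp (%s) must exceed dbp (%s)", s[i], d[i]))
      }
      key <- paste(r$patient_id, r$date)
      for (i in which(duplicated(key))) {
        note("records", i, "date",
             sprintf("duplicate record for patient %s on %s", r$patient_id[i], r$date[i]))
      }
    }
  }
  if (!is.null(patients)) {
    p <- load(patients, "patients")
    need <- c("patient_id", "sex", "age_years", "first_dialysis_date",
              "pd_duration_years", "hf_date")
    miss <- setdiff(need, names(p))
    if (length(miss) > 0) {
      note("patients", NA, paste(miss, collapse = ","), "missing required column(s)")
    } else {
      chk_date("patients", p, "first_dialysis_date")
      chk_date("patients", p, "hf_date")
      a <- chk_num("patients", p, "age_years")
      pd <- chk_num("patients", p, "pd_duration_years")
      for (i in which(!is.na(pd) & pd <= 0)) {
        note("patients", i, "pd_duration_years", "dialysis duration must be > 0")
      }
      for (i in which(!(p$sex %in% c("male", "female")))) {
        note("patients", i, "sex", sprintf("sex must be male/female, got '%s'", p$sex[i]))
      }
      for (i in which(duplicated(p$patient_id))) {
        note("patients", i, "patient_id", sprintf("duplicate patient id %s", p$patient_id[i]))
      }
    }
  }
  if (length(diags) == 0) {
    return(data.frame(table = character(), row = integer(),
                      column = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, diags)
}
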