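# Validation metrics: confusion-matrix summaries, ROC/AUC with DeLong
# confidence intervals, decision-curve analysis, and the case:control ratio
# sensitivity analysis.

# Mann-Whitney rank AUC with tie correction (midranks)
.auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_proc_roc <- function(scores, labels) {
  pROC::roc(response = factor(labels, levels = c(0, 1)), predictor = scores,
            levels = c("0", "1"), direction = "<", quiet = TRUE)
}

#' Confusion-matrix summary metrics
#'
#' Sensitivity `TP / (TP + FN)`, specificity `TN / (FP + TN)`, accuracy
#' `(TP + TN) / n`, and the Youden index `sensitivity + specificity - 1`.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return List of class `pdhf_metrics` with the four metrics and the counts.
#'   An empty class (`tp + fn == 0` or `fp + tn == 0`) raises an error of
#'   class `pdhf_undefined_metric` rather than returning a silent zero.
#' @examples
#' confusion_metrics(tp = 75, fn = 25, tn = 91, fp = 9)$youden  # 0.66
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!vapply(counts, .is_count, logical(1)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (tp + fn == 0 || fp + tn == 0) {
    stop(structure(class = c("pdhf_undefined_metric", "error", "condition"),
                   list(message = "empty class: sensitivity/specificity undefined",
                        call = NULL)))
  }
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = sens, specificity = spec,
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    youden = sens + spec - 1
  ), class = "pdhf_metrics")
}

#' @export
print.pdhf_metrics <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.3f, specificity %.3f, accuracy %.3f, Youden %.3f (tp %d fp %d fn %d tn %d)\n",
    x$sensitivity, x$specificity, x$accuracy, x$youden, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' The AUC point estimate uses the Mann-Whitney rank formulation with midrank
#' tie correction; the confidence interval uses the asymptotic DeLong
#' variance for correlated ROC curves.
#'
#' @param scores Numeric risk scores (higher = more case-like).
#' @param labels 0/1 outcome labels; both classes must be present.
#' @param conf_level Confidence level for the AUC interval.
#' @return List of class `pdhf_roc`: `auc`, `ci` (`lower`, `upper`), and the
#'   ROC `curve` data frame (`threshold`, `fpr`, `tpr`), monotone in both
#'   coordinates.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  auc <- .auc_rank(scores, labels)
  ci <- tryCatch(suppressWarnings({
    r <- .as_proc_roc(scores, labels)
    as.numeric(pROC::ci.auc(r, conf.level = conf_level, method = "delong"))[c(1, 3)]
  }), error = function(e) c(NA_real_, NA_real_))
  # ROC polyline over the distinct score thresholds, descending
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- vapply(thr, function(cc) sum(scores >= cc & labels == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(cc) sum(scores >= cc & labels == 0) / n0, numeric(1))
  structure(list(auc = auc, ci = c(lower = ci[1], upper = ci[2]),
                 conf_level = conf_level,
                 curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "pdhf_roc")
}

#' @export
print.pdhf_roc <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f)\n", x$auc,
              100 * x$conf_level, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Paired comparison of two correlated AUCs
#'
#' DeLong's test for two ROC curves computed from the same subjects.
#'
#' @param scores1,scores2 Score vectors over the same subjects.
#' @param labels Common 0/1 labels.
#' @return List with `auc1`, `auc2`, `statistic`, `p_value`.
#' @export
compare_auc <- function(scores1, scores2, labels) {
  labels <- as.integer(labels)
  r1 <- .as_proc_roc(scores1, labels)
  r2 <- .as_proc_roc(scores2, labels)
  tst <- tryCatch(
    pROC::roc.test(r1, r2, method = "delong", paired = TRUE),
    error = function(e) NULL)
  if (is.null(tst) || is.na(tst$p.value)) {
    # degenerate case (e.g. identical or perfectly separating scores)
    return(list(auc1 = .auc_rank(scores1, labels),
                auc2 = .auc_rank(scores2, labels),
                statistic = 0, p_value = 1))
  }
  list(auc1 = as.numeric(pROC::auc(r1)), auc2 = as.numeric(pROC::auc(r2)),
       statistic = unname(tst$statistic), p_value = tst$p.value)
}

#' Decision-curve analysis
#'
#' Net benefit of treating according to `scores >= pt` at each threshold
#' probability `pt`: `TP/n - (FP/n) * pt / (1 - pt)`, together with the
#' treat-all and treat-none reference policies.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels.
#' @param thresholds Threshold probabilities in (0, 1); values at 0 or 1 are
#'   excluded with a warning.
#' @return Data frame `threshold`, `net_benefit_model`, `net_benefit_all`,
#'   `net_benefit_none`.
#' @export
decision_curve <- function(scores, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  labels <- as.integer(labels)
  bad <- thresholds <= 0 | thresholds >= 1
  if (any(bad)) {
    warning("excluding ", sum(bad), " threshold(s) outside (0, 1)", call. = FALSE)
    thresholds <- thresholds[!bad]
  }
  n <- length(labels)
  prev <- mean(labels)
  nb_model <- vapply(thresholds, function(pt) {
    pred <- scores >= pt
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    tp / n - (fp / n) * pt / (1 - pt)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds,
             net_benefit_model = nb_model,
             net_benefit_all = nb_all,
             net_benefit_none = 0)
}

#' Youden-optimal classification threshold
#'
#' The score cutoff (classify positive when `score >= cutoff`) maximizing
#' sensitivity + specificity - 1. Ties take the lowest cutoff.
#'
#' @param scores Scores on which the threshold is defined.
#' @param labels 0/1 labels.
#' @return A single numeric cutoff.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stopifnot(n1 > 0, n0 > 0)
  j <- vapply(cand, function(cc) {
    sum(scores >= cc & labels == 1) / n1 +
      sum(scores < cc & labels == 0) / n0 - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Evaluate a fitted model on validation rows
#'
#' Scores the rows with the model's predicted probabilities, classifies at
#' the requested threshold, and assembles the full metric report: confusion
#' metrics, ROC with AUC and DeLong CI, and the decision curve.
#'
#' @param model An `hf_model`.
#' @param rows Validation analysis rows (both classes present).
#' @param threshold `"youden"` (default: Youden-optimal cutoff on the model's
#'   own training scores), or a numeric probability cutoff.
#' @param dca_thresholds Threshold grid for the decision curve.
#' @return Object of class `pdhf_report`: threshold used, counts, the four
#'   confusion metrics, `auc` + `auc_ci`, `roc` curve points, and
#'   `decision_curve`.
#' @export
evaluate_model <- function(model, rows, threshold = "youden",
                           dca_thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (nrow(rows) == 0) stop("validation rows are empty", call. = FALSE)
  scores <- predict(model, rows)
  labels <- as.integer(rows$hf_label)
  if (length(unique(labels)) < 2) {
    stop("validation rows must contain both classes", call. = FALSE)
  }
  thr <- if (identical(threshold, "youden")) {
    youden_threshold(model$training$scores, model$training$labels)
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    threshold
  } else {
    stop("threshold must be \"youden\" or a single numeric cutoff", call. = FALSE)
  }
  pred <- scores >= thr
  m <- confusion_metrics(tp = sum(pred & labels == 1),
                         fp = sum(pred & labels == 0),
                         fn = sum(!pred & labels == 1),
                         tn = sum(!pred & labels == 0))
  roc <- roc_auc(scores, labels)
  structure(list(
    threshold_policy = if (identical(threshold, "youden")) "youden" else "fixed",
    threshold = thr,
    tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
    sensitivity = m$sensitivity, specificity = m$specificity,
    accuracy = m$accuracy, youden = m$youden,
    auc = roc$auc, auc_ci = roc$ci, roc = roc$curve,
    decision_curve = decision_curve(scores, labels, dca_thresholds),
    n = length(labels), n_cases = sum(labels)
  ), class = "pdhf_report")
}

#' @export
print.pdhf_report <- function(x, ...) {
  cat(sprintf(
    paste0("<pdhf_report> n = %d (%d cases), threshold %.3f (%s)\n",
           "  sensitivity %.2f, specificity %.2f, accuracy %.2f, Youden %.2f\n",
           "  AUC %.3f (95%% CI %.3f-%.3f)\n"),
    x$n, x$n_cases, x$threshold, x$threshold_policy,
    x$sensitivity, x$specificity, x$accuracy, x$youden,
    x$auc, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' Case:control ratio sensitivity analysis
#'
#' Re-runs the study construction, four-model fit, optimal-model selection
#' and validation for each requested control ratio, keeping every case. Each
#' ratio uses seeds offset by the ratio so the case rows are identical across
#' ratios while the control draws are re-randomized.
#'
#' @param cohort A `pdhf_cohort`.
#' @param flags [discretize_cohort()] output covering alphas 0.05 and 0.01.
#' @param ratios Integer control ratios (1:R designs).
#' @param seed_sample,seed_split Base seeds for the control draw and split.
#' @param train_frac Training fraction.
#' @param alpha_stay Backward-elimination stay threshold.
#' @param threshold Classification threshold policy (see [evaluate_model()]).
#' @param variables Candidate variables.
#' @return Named list (one element per ratio). Each successful element has
#'   `ratio`, `n_rows`, `model_id`, `retained` variables, `training_auc`,
#'   `auc`, `auc_ci`, `youden`, `report`; failed ratios carry `error` and do
#'   not abort the others.
#' @export
sensitivity_analysis <- function(cohort, flags, ratios = c(4, 6, 10),
                                 seed_sample = 1L, seed_split = 2L,
                                 train_frac = 0.8, alpha_stay = 0.05,
                                 threshold = "youden",
                                 variables = hf_candidate_variables()) {
  rows05 <- build_rows(cohort, flags, 0.05)
  rows99 <- build_rows(cohort, flags, 0.01)
  out <- lapply(ratios, function(r) {
    tryCatch({
      samp99 <- sample_case_control(rows99, ratio = r, seed = seed_sample + r)
      samp99 <- split_train_validation(samp99, train_frac = train_frac,
                                       seed = seed_split + r)
      samp05 <- rows05[match(samp99$patient_id, rows05$patient_id), , drop = FALSE]
      samp05$split <- samp99$split
      models <- fit_hf_models(samp05, samp99, variables = variables,
                              alpha_stay = alpha_stay)
      opt <- select_optimal(models)
      val <- if (opt$spec$alpha_criterion == 0.05) samp05 else samp99
      val <- val[val$split == "validation", , drop = FALSE]
      rep <- evaluate_model(opt, val, threshold = threshold)
      list(ratio = r, n_rows = nrow(samp99), model_id = opt$spec$id,
           retained = opt$variables, training_auc = opt$training$auc,
           auc = rep$auc, auc_ci = rep$auc_ci, youden = rep$youden,
           models = models, report = rep)
    }, error = function(e) list(ratio = r, error = conditionMessage(e)))
  })
  names(out) <- paste0("ratio_", ratios)
  out
}
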