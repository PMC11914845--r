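# The four candidate logistic prediction models.
#
# Models 1 and 2 use the 95%-criterion categories, models 3 and 4 the
# 99%-criterion categories; models 1 and 3 enter all candidate variables,
# models 2 and 4 apply backward elimination keeping only variables with a
# Wald p-value below `alpha_stay`. The optimal model has the lowest AIC; when
# it is not also the model with the highest training AUC, the two are
# compared by the paired DeLong test and the lowest-AIC model is kept unless
# the AUC difference is significant.

.model_column <- c(sex = "sex", age = "age", pd_duration = "pd_duration",
                   weight_cat = "weight_cat", urine_cat = "urine_cat",
                   sbp_cat = "sbp_cat", dbp_cat = "dbp_cat", pp_cat = "pp_cat")

# term name in the glm coefficient table for each candidate variable
.model_term <- c(sex = "sexfemale", age = "age", pd_duration = "pd_duration",
                 weight_cat = "weight_catabnormal",
                 urine_cat = "urine_catabnormal",
                 sbp_cat = "sbp_catabnormal", dbp_cat = "dbp_catabnormal",
                 pp_cat = "pp_catabnormal")

#' Specifications of the four candidate models
#'
#' @return Data frame with columns `id`, `alpha_criterion`, `selection`.
#' @export
hf_model_specs <- function() {
  data.frame(id = 1:4,
             alpha_criterion = c(0.05, 0.05, 0.01, 0.01),
             selection = c("all_variables", "backward",
                           "all_variables", "backward"),
             stringsAsFactors = FALSE)
}

#' Fit a logistic heart-failure prediction model
#'
#' Maximum-likelihood logistic regression of the heart-failure label on the
#' given candidate variables. References: male for sex, normal for the
#' categorical vitals; age and dialysis duration enter untransformed.
#' Constant-valued variables are dropped with a warning. Complete or
#' quasi-complete separation (non-convergence, exploding coefficients or
#' standard errors) triggers a ridge-penalized refit, marked on the result.
#'
#' Adjusted odds ratios are `exp(coef)` with Wald 95% CIs
#' `exp(coef +/- 1.96 * SE)`; AIC is `2k - 2 logLik` with `k` counting the
#' intercept.
#'
#' @param rows Analysis rows ([build_rows()]); rows with `split` defined are
#'   used as-is (no filtering here).
#' @param variables Candidate variables, a subset of
#'   [hf_candidate_variables()]. May be empty (intercept-only model).
#' @param ridge_lambda Penalty used only by the separation fallback.
#' @return Object of class `hf_model`: coefficient table (`estimate`, `se`,
#'   `z`, `p`, `aor`, `ci_lower`, `ci_upper`), `loglik`, `aic`,
#'   `training` scores/labels/AUC, fitted glm, and bookkeeping
#'   (`dropped`, `penalized`).
#' @export
fit_logistic <- function(rows, variables = hf_candidate_variables(),
                         ridge_lambda = 0.01) {
  stopifnot(all(variables %in% names(.model_column)))
  y <- rows$hf_label
  if (length(unique(y)) < 2) {
    stop("need at least one case and one control to fit", call. = FALSE)
  }
  dropped <- character(0)
  for (v in variables) {
    col <- rows[[.model_column[[v]]]]
    if (length(unique(as.character(col[!is.na(col)]))) < 2) {
      dropped <- c(dropped, v)
    }
  }
  if (length(dropped) > 0) {
    warning("dropping constant variable(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    variables <- setdiff(variables, dropped)
  }
  dat <- rows[, unname(.model_column[variables]), drop = FALSE]
  dat$hf_label <- y
  form <- if (length(variables) > 0) {
    stats::as.formula(paste("hf_label ~", paste(.model_column[variables], collapse = " + ")))
  } else {
    hf_label ~ 1
  }

  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(form, data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  separated <- sep_warn || !fit$converged || any(abs(est) > 15) || any(se > 50)
  penalized <- FALSE
  if (separated) {
    X <- stats::model.matrix(form, dat)
    rf <- .ridge_logistic(X, y, lambda = ridge_lambda)
    est <- rf$coef; se <- rf$se
    penalized <- TRUE
    warning("separation detected; ridge-penalized fit used (lambda = ",
            ridge_lambda, ")", call. = FALSE)
  }

  p_hat <- if (penalized) {
    as.vector(plogis(stats::model.matrix(form, dat) %*% est))
  } else {
    fitted(fit)
  }
  ll <- sum(y * log(pmax(p_hat, 1e-300)) + (1 - y) * log(pmax(1 - p_hat, 1e-300)))
  k <- length(est)
  z <- est / se
  ct <- data.frame(
    term = names(est),
    estimate = unname(est), se = unname(se), z = unname(z),
    p = unname(2 * pnorm(-abs(z))),
    aor = unname(exp(est)),
    ci_lower = unname(exp(est - 1.96 * se)),
    ci_upper = unname(exp(est + 1.96 * se)),
    stringsAsFactors = FALSE
  )
  structure(list(
    variables = variables, dropped = dropped, formula = form,
    coef = ct, loglik = ll, aic = 2 * k - 2 * ll, k = k,
    n = nrow(dat), n_cases = sum(y), penalized = penalized,
    glm = fit, ridge_coef = if (penalized) est else NULL,
    training = list(scores = p_hat, labels = y, auc = .auc_rank(p_hat, y))
  ), class = "hf_model")
}

# Newton-Raphson ridge logistic regression (penalty on non-intercept terms);
# SE from the penalized information matrix
.ridge_logistic <- function(X, y, lambda = 0.01, max_iter = 100, tol = 1e-10) {
  k <- ncol(X)
  pen <- diag(rep(lambda, k)); pen[1, 1] <- 0
  beta <- rep(0, k)
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    g <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- solve(H, g)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  V <- solve(crossprod(X * plogis(as.vector(X %*% beta)) *
                         (1 - plogis(as.vector(X %*% beta))), X) + pen)
  list(coef = stats::setNames(as.vector(beta), colnames(X)),
       se = stats::setNames(sqrt(diag(V)), colnames(X)))
}

#' @export
print.hf_model <- function(x, ...) {
  cat(sprintf("<hf_model> %s ~ %s\n",
              "hf_label",
              if (length(x$variables)) paste(x$variables, collapse = " + ") else "1"))
  cat(sprintf("  n = %d (%d cases), logLik = %.3f, AIC = %.2f, training AUC = %.3f%s\n",
              x$n, x$n_cases, x$loglik, x$aic, x$training$auc,
              if (x$penalized) " [ridge fallback]" else ""))
  print(x$coef, digits = 4)
  invisible(x)
}

#' Predicted heart-failure probabilities
#'
#' @param object An `hf_model`.
#' @param newdata Analysis rows.
#' @param ... Unused.
#' @return Numeric vector of predicted probabilities.
#' @export
predict.hf_model <- function(object, newdata, ...) {
  if (object$penalized) {
    rhs <- stats::delete.response(stats::terms(object$formula))
    X <- stats::model.matrix(rhs,
                             newdata[, unname(.model_column[object$variables]),
                                     drop = FALSE])
    as.vector(plogis(X %*% object$ridge_coef))
  } else {
    as.vector(predict(object$glm, newdata = newdata, type = "response"))
  }
}

# Wald p-value per candidate variable (each maps to a single coefficient)
.variable_p <- function(model) {
  vars <- model$variables
  terms <- .model_term[vars]
  p <- model$coef$p[match(terms, model$coef$term)]
  stats::setNames(p, vars)
}

#' Backward elimination of candidate variables
#'
#' Starting from the full model, repeatedly refits after removing the
#' variable with the largest Wald p-value at or above `alpha_stay`, until all
#' retained variables are significant. When several variables tie for the
#' largest p-value, the one listed first in `variables` is removed
#' (deterministic tie-break). If everything is eliminated the intercept-only
#' model is returned with a warning.
#'
#' @inheritParams fit_logistic
#' @param alpha_stay Significance level a variable must beat to stay.
#' @return An `hf_model` for the retained variables, with attribute
#'   `elimination_path` recording the removals.
#' @export
backward_select <- function(rows, variables = hf_candidate_variables(),
                            alpha_stay = 0.05, ridge_lambda = 0.01) {
  vars <- variables
  path <- character(0)
  repeat {
    fit <- fit_logistic(rows, vars, ridge_lambda = ridge_lambda)
    vars <- fit$variables  # constants may have been dropped
    if (length(vars) == 0) {
      warning("all variables eliminated; returning intercept-only model",
              call. = FALSE)
      break
    }
    p <- .variable_p(fit)
    worst <- max(p)
    if (worst < alpha_stay) break
    drop_var <- vars[which(p == worst)[1L]]
    path <- c(path, drop_var)
    vars <- setdiff(vars, drop_var)
    if (length(vars) == 0) {
      warning("all variables eliminated; returning intercept-only model",
              call. = FALSE)
      fit <- fit_logistic(rows, character(0))
      break
    }
  }
  attr(fit, "elimination_path") <- path
  fit
}

#' Fit the four candidate models
#'
#' @param rows05,rows99 Analysis rows built at the 95% and 99% criteria for
#'   the same patients (same order); rows with a `split` column are filtered
#'   to `split == "train"`.
#' @param variables Candidate variables.
#' @param alpha_stay Backward-elimination stay threshold.
#' @param ridge_lambda Separation fallback penalty.
#' @return List of four `hf_model`s; each carries a `spec` element
#'   (`id`, `alpha_criterion`, `selection`).
#' @export
fit_hf_models <- function(rows05, rows99,
                          variables = hf_candidate_variables(),
                          alpha_stay = 0.05, ridge_lambda = 0.01) {
  pick_train <- function(r) {
    if (!is.null(r$split)) r[r$split == "train", , drop = FALSE] else r
  }
  tr05 <- pick_train(rows05)
  tr99 <- pick_train(rows99)
  if (!identical(tr05$patient_id, tr99$patient_id)) {
    stop("rows05 and rows99 must cover the same patients in the same order",
         call. = FALSE)
  }
  specs <- hf_model_specs()
  models <- vector("list", 4L)
  for (i in 1:4) {
    rows_i <- if (specs$alpha_criterion[i] == 0.05) tr05 else tr99
    m <- if (specs$selection[i] == "all_variables") {
      fit_logistic(rows_i, variables, ridge_lambda = ridge_lambda)
    } else {
      backward_select(rows_i, variables, alpha_stay = alpha_stay,
                      ridge_lambda = ridge_lambda)
    }
    m$spec <- as.list(specs[i, ])
    models[[i]] <- m
  }
  models
}

#' Select the optimal model by AIC and AUC
#'
#' Ranks models by AIC (lower is better). If the lowest-AIC model also has
#' the highest training AUC it is selected outright; otherwise its training
#' ROC is compared with the highest-AUC model's by the paired DeLong test,
#' and the lowest-AIC model is kept when the difference is not significant at
#' `alpha`, the higher-AUC model otherwise. The comparison is recorded in the
#' `selection` attribute.
#'
#' @param models List of `hf_model`s fitted on the same patients.
#' @param alpha Significance level for the paired AUC comparison.
#' @return The selected `hf_model`, with attribute `selection`.
#' @export
select_optimal <- function(models, alpha = 0.05) {
  stopifnot(length(models) >= 1)
  if (length(models) == 1L) return(models[[1L]])
  aics <- vapply(models, function(m) m$aic, numeric(1))
  aucs <- vapply(models, function(m) m$training$auc, numeric(1))
  i_aic <- which.min(aics)
  i_auc <- which.max(aucs)
  info <- list(aic = aics, auc = aucs, by_aic = i_aic, by_auc = i_auc,
               comparison = NULL)
  if (i_aic == i_auc) {
    out <- models[[i_aic]]
  } else {
    cmp <- compare_auc(models[[i_aic]]$training$scores,
                       models[[i_auc]]$training$scores,
                       models[[i_aic]]$training$labels)
    info$comparison <- cmp
    out <- if (cmp$p_value >= alpha) models[[i_aic]] else models[[i_auc]]
    message(sprintf(
      "lowest-AIC model %d vs highest-AUC model %d: DeLong p = %.3f; selected model %d",
      i_aic, i_auc, cmp$p_value,
      if (cmp$p_value >= alpha) i_aic else i_auc))
  }
  attr(out, "selection") <- info
  out
}
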