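test_that("logistic fits recover known coefficients", {
  rows <- simulate_analysis_rows(4000, seed = 61)
  truth <- attr(rows, "true_coef")
  m <- fit_logistic(rows, c("sex", "age", "dbp_cat"))
  ct <- m$coef
  for (pair in list(c("sexfemale", "female"), c("age", "age"),
                    c("dbp_catabnormal", "dbp_abnormal"))) {
    est <- ct$estimate[ct$term == pair[1]]
    se <- ct$se[ct$term == pair[1]]
    expect_lt(abs(est - truth[[pair[2]]]), 3.5 * se)
  }
  # adjusted odds ratios and Wald intervals are exact transforms
  expect_equal(ct$aor, exp(ct$estimate), tolerance = 1e-12)
  expect_equal(ct$ci_lower, exp(ct$estimate - 1.96 * ct$se), tolerance = 1e-12)
  expect_equal(ct$ci_upper, exp(ct$estimate + 1.96 * ct$se), tolerance = 1e-12)
})

test_that("AIC equals 2k - 2logL via an independent likelihood oracle", {
  withr::with_seed(71, {
    for (i in 1:20) {
      rows <- simulate_analysis_rows(sample(150:400, 1))
      vars <- sample(c("sex", "age", "pd_duration", "dbp_cat"),
                     sample(1:4, 1))
      m <- suppressWarnings(fit_logistic(rows, vars))
      p <- predict(m, rows)
      expect_equal(m$aic, oracle_aic(p, rows$hf_label, m$k), tolerance = 1e-8)
      expect_equal(m$loglik, oracle_loglik(p, rows$hf_label), tolerance = 1e-8)
      if (!m$penalized) expect_equal(m$aic, AIC(m$glm), tolerance = 1e-8)
    }
  })
})

test_that("degenerate inputs are refused or repaired", {
  rows <- simulate_analysis_rows(200, seed = 5)
  rows$hf_label <- 0L
  expect_error(fit_logistic(rows, c("sex", "age")), "case")
  rows2 <- simulate_analysis_rows(200, seed = 6)
  rows2$weight_cat <- factor("normal", levels = c("normal", "abnormal"))
  expect_warning(m <- fit_logistic(rows2, c("sex", "age", "weight_cat")),
                 "constant")
  expect_false("weight_cat" %in% m$variables)
})

test_that("complete separation falls back to a marked ridge fit", {
  rows <- simulate_analysis_rows(300, seed = 12)
  rows$dbp_cat <- factor(ifelse(rows$hf_label == 1, "abnormal", "normal"),
                         levels = c("normal", "abnormal"))
  expect_warning(m <- fit_logistic(rows, c("dbp_cat")), "ridge")
  expect_true(m$penalized)
  expect_true(all(is.finite(m$coef$se)))
  p <- predict(m, rows)
  expect_true(all(p > 0 & p < 1))
})

test_that("backward elimination keeps exactly the informative variables", {
  res <- withr::with_seed(81, {
    replicate(20, {
      rows <- simulate_analysis_rows(1500)
      m <- suppressWarnings(backward_select(rows))
      paste(sort(m$variables), collapse = "+")
    })
  })
  tab <- sort(table(res), decreasing = TRUE)
  expect_identical(names(tab)[1], "age+dbp_cat+sex")
  expect_gt(tab[1] / 20, 0.5)
})

test_that("backward elimination on pure noise usually empties the model", {
  res <- withr::with_seed(91, {
    replicate(30, {
      rows <- simulate_analysis_rows(
        2000, coef = c(intercept = -2, female = 0, age = 0, dbp_abnormal = 0))
      m <- suppressWarnings(backward_select(rows))
      length(m$variables)
    })
  })
  expect_gte(mean(res == 0), 0.5)
  expect_lt(mean(res), 1)
})

test_that("a single significant predictor passes through unchanged", {
  rows <- simulate_analysis_rows(2000, seed = 101)
  m <- backward_select(rows, "dbp_cat")
  expect_identical(m$variables, "dbp_cat")
  expect_identical(attr(m, "elimination_path"), character(0))
})

test_that("candidate order only matters through the documented tie-break", {
  rows <- simulate_analysis_rows(800, seed = 111)
  a <- suppressWarnings(backward_select(rows, hf_candidate_variables()))
  b <- suppressWarnings(backward_select(rows, rev(hf_candidate_variables())))
  expect_setequal(a$variables, b$variables)
})

test_that("the four model specifications map criteria and selection correctly", {
  specs <- hf_model_specs()
  expect_identical(specs$alpha_criterion, c(0.05, 0.05, 0.01, 0.01))
  expect_identical(specs$selection,
                   c("all_variables", "backward", "all_variables", "backward"))
  co <- generate_cohort(test_config(n = 500, seed = 121))
  fl <- discretize_cohort(co)
  r05 <- split_train_validation(sample_case_control(build_rows(co, fl, 0.05), 3, seed = 1),
                                seed = 2)
  r99 <- build_rows(co, fl, 0.01)
  r99 <- r99[match(r05$patient_id, r99$patient_id), ]
  r99$split <- r05$split
  models <- suppressWarnings(fit_hf_models(r05, r99))
  expect_length(models, 4L)
  expect_identical(vapply(models, function(m) m$spec$id, integer(1)), 1:4)
  expect_setequal(models[[1]]$variables,
                  setdiff(hf_candidate_variables(), models[[1]]$dropped))
  expect_true(all(models[[2]]$variables %in% models[[1]]$variables))
  # backward models only keep significant variables
  for (m in models[c(2, 4)]) {
    if (length(m$variables) > 0) {
      p <- pdhf:::.variable_p(m)
      expect_true(all(p < 0.05))
    }
  }
})

test_that("model selection prefers the lowest AIC unless AUC clearly disagrees", {
  mock <- function(id, aic, scores, labels) {
    structure(list(spec = list(id = id), aic = aic,
                   variables = "x",
                   training = list(scores = scores, labels = labels,
                                   auc = pdhf:::.auc_rank(scores, labels))),
              class = "hf_model")
  }
  labels <- rep(c(1, 0), c(40, 200))
  s_strong <- withr::with_seed(1, plogis(2 * labels + rnorm(240)))
  # a noisy, slightly better variant: higher AUC, non-significant difference
  s_similar <- withr::with_seed(103, plogis(qlogis(s_strong) + 0.05 * rnorm(240)))
  s_noise <- withr::with_seed(2, runif(240))

  single <- mock(1L, 150, s_strong, labels)
  expect_identical(select_optimal(list(single))$spec$id, 1L)

  # lowest AIC and highest AUC coincide
  m1 <- mock(1L, 150, s_noise, labels)
  m2 <- mock(2L, 140, s_strong, labels)
  expect_identical(select_optimal(list(m1, m2))$spec$id, 2L)

  # conflict, non-significant difference: AIC wins
  m3 <- mock(3L, 120, s_strong, labels)
  m4 <- mock(4L, 130, s_similar, labels)
  sel <- suppressMessages(select_optimal(list(m3, m4)))
  expect_identical(sel$spec$id, 3L)
  pcmp <- attr(sel, "selection")$comparison$p_value
  expect_true(is.null(pcmp) || pcmp >= 0.05)

  # conflict, significant difference: AUC wins
  m5 <- mock(5L, 100, s_noise, labels)
  m6 <- mock(6L, 110, s_strong, labels)
  sel2 <- suppressMessages(select_optimal(list(m5, m6)))
  expect_identical(sel2$spec$id, 6L)
})

test_that("selection at the reported AIC pattern picks the fourth model", {
  labels <- rep(c(1, 0), c(39, 225))
  base <- withr::with_seed(3, 2 * labels + rnorm(264))
  models <- Map(function(id, aic, shift) {
    s <- plogis(base + shift * labels)
    structure(list(spec = list(id = id), aic = aic, variables = "x",
                   training = list(scores = s, labels = labels,
                                   auc = pdhf:::.auc_rank(s, labels))),
              class = "hf_model")
  }, 1:4, c(147.23, 138.62, 145.18, 136.50), c(0, 0.01, 0.005, 0.02))
  sel <- suppressMessages(select_optimal(models))
  expect_identical(sel$spec$id, 4L)
})
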