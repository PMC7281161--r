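test_that("cohort split: floor rounding, determinism, partition property", {
  cohort <- tibble::tibble(patient_id = sprintf("P%03d", 1:214),
                           outcome = rep(c("dm", "nonevent"), c(53, 161)))
  sp <- split_cohort(cohort, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 149L)
  expect_equal(nrow(sp$test), 65L)

  sp2 <- split_cohort(cohort, 0.7, seed = 1)
  expect_identical(sp$train$patient_id, sp2$train$patient_id)

  for (s in 1:25) {
    spl <- split_cohort(cohort, 0.7, seed = s)
    ids <- c(spl$train$patient_id, spl$test$patient_id)
    expect_setequal(ids, cohort$patient_id)
    expect_equal(anyDuplicated(ids), 0L)
  }
  expect_error(split_cohort(cohort[1:5, ], 0.7), "too small")
})

make_train <- function(n, d, seed, noise_markers = 0) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, 0.3)
    d_all <- c(d, rep(0, noise_markers))
    X <- vapply(d_all, function(dd) rnorm(n, dd * y), numeric(n))
    colnames(X) <- paste0("m", seq_along(d_all))
    dplyr::bind_cols(tibble::tibble(y = y), tibble::as_tibble(X))
  })
}

test_that("univariable selection applies strict p and AUC gates", {
  # pure-noise marker at n = 500 is excluded
  tr <- make_train(500, 0, seed = 2)
  sel <- univariable_select(tr, "m1", "y")
  expect_false(sel$selected)

  # a marker at exactly the AUC floor is excluded (strict >)
  # 2 positives vs 10 negatives with 13/20 concordant pairs: AUC 0.65
  tr2 <- tibble::tibble(y = rep(c(1, 0), c(2, 10)),
                        m1 = c(11, 3.5, 1:10))
  expect_equal(oracle_auc(tr2$m1, tr2$y), 0.65)
  sel2 <- univariable_select(tr2, "m1", "y")
  expect_equal(sel2$auc, 0.65)
  expect_false(sel2$selected)

  # planted d = 1.19 (population AUC 0.80) at n = 500 is reliably selected
  hits <- vapply(1:20, function(s) {
    univariable_select(make_train(500, 1.19, seed = s), "m1", "y")$selected
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("panel fit: symmetry, coefficient recovery, collinearity fallback", {
  # symmetric class-conditional design: intercept near 0
  sym <- withr::with_seed(4, tibble::tibble(
    y = rep(c(0, 1), each = 2000),
    m1 = rnorm(4000, rep(c(-0.75, 0.75), each = 2000))))
  fit <- fit_panel_classifier(sym, "m1", "y")
  expect_lt(abs(fit$coefficients[["(Intercept)"]]), 0.12)
  expect_false(fit$penalized)

  # planted logistic coefficients recovered within Wald intervals
  dat <- withr::with_seed(11, {
    x <- rnorm(5000)
    tibble::tibble(m1 = x, y = rbinom(5000, 1, plogis(-2 + x)))
  })
  fit2 <- fit_panel_classifier(dat, "m1", "y")
  sm <- summary(fit2$fit)$coefficients
  expect_lt(abs(sm[1, 1] - (-2)), 1.96 * sm[1, 2])
  expect_lt(abs(sm[2, 1] - 1), 1.96 * sm[2, 2])

  # duplicated marker column: penalised fallback, flagged
  dup <- dplyr::mutate(dat, m2 = m1)
  fit3 <- fit_panel_classifier(dup, c("m1", "m2"), "y")
  expect_true(fit3$penalized)
  expect_equal(fit3$reason, "collinear")

  expect_error(fit_panel_classifier(dplyr::mutate(dat, m3 = 1),
                                    c("m1", "m3"), "y"), "m3")
})

test_that("separated data fall back to a penalised fit instead of failing", {
  sep <- tibble::tibble(y = rep(c(0, 1), each = 10),
                        m1 = c(rnorm(10, -3), rnorm(10, 3)))
  fit <- fit_panel_classifier(sep, "m1", "y")
  expect_true(fit$penalized)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("scores live on the 0-100 probability scale", {
  m <- panel_classifier(c(`(Intercept)` = 0, m1 = 1))
  expect_equal(score_patients(m, tibble::tibble(m1 = 0))$score, 50)
  expect_gt(score_patients(m, tibble::tibble(m1 = 50))$score, 99.99)
  expect_lt(score_patients(m, tibble::tibble(m1 = -50))$score, 0.01)
  s <- score_patients(m, tibble::tibble(m1 = seq(-3, 3, 0.5)))$score
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= 0 & s <= 100))
  expect_true(is.na(score_patients(m, tibble::tibble(m1 = NA_real_))$score))
})

test_that("scoring is invariant to affine marker re-encoding", {
  m <- panel_classifier(c(`(Intercept)` = -1, m1 = 0.8))
  x <- rnorm(20)
  s1 <- score_patients(m, tibble::tibble(m1 = x))$score
  # re-encode m1' = 2 x + 3; beta' = beta / 2, intercept' = b0 - 3 beta / 2
  m2 <- panel_classifier(c(`(Intercept)` = -1 - 3 * 0.4, m1 = 0.4))
  s2 <- score_patients(m2, tibble::tibble(m1 = 2 * x + 3))$score
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("threshold metrics come from direct 2x2 counting", {
  # 10 positives / 90 negatives; threshold catching 9 TP and 42 FP
  scores <- c(seq(0.91, 0.99, 0.01), 0.2,            # positives
              runif(42, 0.55, 0.9), runif(48, 0, 0.4))
  labels <- rep(c(1, 0), c(10, 90))
  m <- evaluate_at_threshold(scores, labels, 0.5)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 48 / 90)
  expect_equal(m$npv, 48 / 49)

  hi <- evaluate_at_threshold(scores, labels, 2)
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)
  expect_equal(hi$npv, 1 - 0.1)
  lo <- evaluate_at_threshold(scores, labels, -1)
  expect_equal(lo$sensitivity, 1)
  expect_equal(lo$specificity, 0)
  expect_equal(lo$ppv, 0.1)
  expect_error(evaluate_at_threshold(numeric(0), integer(0), 1), "No")
  expect_error(evaluate_at_threshold(1, 1, Inf), "finite")
})

test_that("bootstrapped threshold equals the constrained search point estimate", {
  scores <- c(rnorm(40, 30, 8), rnorm(20, 70, 8))
  labels <- rep(c(0, 1), c(40, 20))
  th <- bootstrap_threshold(scores, labels, B = 100, seed = 3)
  cp <- constrained_cutpoint(scores, labels, min_npv = 0.9,
                             min_spec = 0.35, direction = "high_risk",
                             B = 100, seed = 3)
  expect_equal(th$threshold, cp$cutpoint)
  expect_identical(
    bootstrap_threshold(scores, labels, B = 100, seed = 3),
    th)
  # perfectly separated toy: threshold at the gap midpoint
  th2 <- bootstrap_threshold(c(1, 2, 8, 9), c(0, 0, 1, 1), B = 10,
                             seed = 1)
  expect_equal(th2$threshold, 5)
  expect_equal(th2$sensitivity, 1)
  expect_equal(th2$specificity, 1)
  # unattainable NPV on overlapping classes
  th3 <- bootstrap_threshold(c(1, 3, 2, 4), c(0, 0, 1, 1), min_npv = 1,
                             strict = TRUE, B = 10, seed = 1)
  expect_false(th3$feasible)
})

test_that("likelihood-ratio comparison of nested logistic models", {
  d <- withr::with_seed(6, tibble::tibble(
    x1 = rnorm(300), x2 = rnorm(300),
    y = rbinom(300, 1, plogis(0.5 * x1))))
  base <- glm(y ~ x1, data = d, family = binomial())
  same <- compare_models_lrt(base, base)
  expect_equal(same$chi_squared, 0)
  expect_equal(same$p_value, 1)

  full <- glm(y ~ x1 + x2, data = d, family = binomial())
  lrt <- compare_models_lrt(base, full)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$chi_squared,
               as.numeric(2 * (logLik(full) - logLik(base))),
               tolerance = 1e-10)

  d2 <- d[1:200, ]
  base2 <- glm(y ~ x1, data = d2, family = binomial())
  expect_error(compare_models_lrt(base2, full), "different numbers")
  expect_error(compare_models_lrt(full, base), "not nested")
})

test_that("a strongly predictive added covariate is detected by the LRT", {
  hits <- vapply(1:10, function(s) {
    d <- withr::with_seed(s, tibble::tibble(
      x1 = rnorm(2000), x2 = rnorm(2000),
      y = rbinom(2000, 1, plogis(-1 + 0.3 * x1 + x2))))
    base <- glm(y ~ x1, data = d, family = binomial())
    full <- glm(y ~ x1 + x2, data = d, family = binomial())
    compare_models_lrt(base, full)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

make_survival_cohort <- function(n, beta_score, seed) {
  withr::with_seed(seed, {
    score <- runif(n, 0, 100)
    rate <- 0.01 * exp(beta_score * score)
    t_ev <- rexp(n, rate)
    t_c <- runif(n, 0, 200)
    tibble::tibble(
      age_at_dx = rnorm(n, 60, 7),
      race = sample(c("AA", "CA_other"), n, replace = TRUE),
      nccn = sample(c("low", "intermediate", "high"), n, replace = TRUE),
      path_t = sample(c("pT2", "pT3-4"), n, replace = TRUE),
      grade_group = sample(1:5, n, replace = TRUE),
      margin = sample(c("neg", "pos"), n, replace = TRUE),
      score = score,
      dm_time = pmin(t_ev, t_c),
      dm_event = as.integer(t_ev <= t_c))
  })
}

test_that("Cox fit recovers a planted continuous hazard ratio", {
  beta <- log(2) / 10   # HR 2 per 10 score units
  d <- make_survival_cohort(2000, beta, seed = 21)
  fit <- cox_classifier(d, "dm_time", "dm_event", soc = "biopsy",
                        classifier = "continuous")
  hr10 <- tidy(fit) |>
    dplyr::filter(.data$term == "classifier") |>
    dplyr::pull(.data$hr)
  expect_lt(abs(hr10^10 - 2), 0.25)
  # PH diagnostics are reported
  expect_true(nrow(fit$ph_test) >= 1)
})

test_that("Cox hazard ratios are invariant to rescaling time", {
  d <- make_survival_cohort(400, log(2) / 10, seed = 22)
  f1 <- cox_classifier(d, "dm_time", "dm_event", soc = "pathology",
                       classifier = "continuous")
  d2 <- dplyr::mutate(d, dm_time = 2 * dm_time)
  f2 <- cox_classifier(d2, "dm_time", "dm_event", soc = "pathology",
                       classifier = "continuous")
  expect_equal(tidy(f1)$hr, tidy(f2)$hr, tolerance = 1e-8)
})

test_that("Cox dichotomous form uses the threshold and drops constants", {
  d <- make_survival_cohort(300, log(2) / 10, seed = 23) |>
    dplyr::mutate(margin = "neg")
  expect_warning(
    fit <- cox_classifier(d, "dm_time", "dm_event", soc = "pathology",
                          classifier = "dichotomous", threshold = 50),
    "margin")
  expect_true("classifierhigh" %in% tidy(fit)$term)
  expect_error(cox_classifier(d, "dm_time", "dm_event",
                              classifier = "dichotomous"), "threshold")
})

test_that("end-to-end training produces a constraint-satisfying threshold", {
  sim <- simulate_cohort(sim_config(n_patients = 300), seed = 31)
  dmne <- dplyr::filter(sim$cohort, outcome %in% c("dm", "nonevent")) |>
    dplyr::mutate(y = as.integer(outcome == "dm"))
  model <- train_classifier(dmne, default_marker_effects()$marker, "y",
                            B = 40, seed = 31)
  expect_true(model$threshold_feasible)
  expect_gte(model$train_metrics$npv, 0.90)
  expect_gte(model$train_metrics$specificity, 0.35)
  expect_true(model$threshold >= 0 && model$threshold <= 100)
  expect_length(model$threshold_ci, 2L)
  # refit-mode threshold point estimate matches the fixed-score search
  scored <- score_patients(model, dmne)
  cp <- bootstrap_threshold(scored$score, dmne$y, B = 0)
  expect_equal(model$threshold, cp$threshold)
})

test_that("classifier JSON round-trips through serialisation", {
  m <- panel_classifier(c(`(Intercept)` = -2.5, SPARC = 1.2,
                          TGFB1 = 0.7), threshold = 8.3)
  m$threshold_ci <- c(6.1, 11.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier_json(m, path)
  m2 <- read_classifier_json(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$threshold, 8.3)
  d <- tibble::tibble(SPARC = c(-1, 0, 2), TGFB1 = c(0, 1, 1))
  expect_equal(score_patients(m, d)$score, score_patients(m2, d)$score)
})
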