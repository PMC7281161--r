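#' Random train/test split of a cohort
#'
#' Simple (non-stratified) random split; the training set takes
#' `floor(train_fraction * n)` patients, so a 214-patient cohort at 0.7
#' splits 149/65. Seeded splits are reproducible.
#'
#' @param cohort Data frame of patients.
#' @param train_fraction Fraction allocated to training (default 0.7).
#' @param outcome Optional outcome column; if either partition ends up
#'   single-class a warning is raised and recorded.
#' @param seed Optional integer seed.
#' @return List of class `cohort_split`: `train`, `test`,
#'   `single_class` (logical flag).
#' @export
split_cohort <- function(cohort, train_fraction = 0.7, outcome = NULL,
                         seed = NULL) {
  n <- nrow(cohort)
  if (n < 10L) abort("Cohort too small to split (n < 10).")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie in (0, 1).")
  }
  n_train <- floor(train_fraction * n)
  idx <- with_seed_if(seed, sample.int(n, n_train))
  train <- cohort[sort(idx), , drop = FALSE]
  test <- cohort[setdiff(seq_len(n), idx), , drop = FALSE]
  single <- FALSE
  if (!is.null(outcome)) {
    single <- dplyr::n_distinct(train[[outcome]]) < 2L ||
      dplyr::n_distinct(test[[outcome]]) < 2L
    if (single) warn("A partition contains a single outcome class.")
  }
  structure(list(train = tibble::as_tibble(train),
                 test = tibble::as_tibble(test),
                 single_class = single),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("Cohort split: train n =", nrow(x$train),
      "/ test n =", nrow(x$test), "\n")
  invisible(x)
}

#' Univariable marker selection by logistic regression
#'
#' Fits one logistic regression per candidate marker and keeps those with
#' Wald p-value below `p_max` and AUC strictly above `auc_min` (both
#' strict, so a marker at exactly the AUC floor is excluded). With
#' `orient = TRUE` (default) the gate uses the oriented AUC
#' `max(a, 1 - a)`, the convention under which protective markers (lower
#' values in events) are reported; the logistic coefficient sign carries
#' the direction into the panel fit either way. Non-convergent fits are
#' excluded with a note.
#'
#' @param train Training tibble.
#' @param markers Candidate marker columns.
#' @param outcome Binary outcome column.
#' @param positive Positive-class label (see [marker_auc()]).
#' @param p_max Wald p-value ceiling (default 0.05, exclusive).
#' @param auc_min AUC floor (default 0.65, exclusive).
#' @param orient Apply the AUC gate on the oriented scale?
#' @return Tibble: `marker`, `estimate`, `p_value`, `auc` (raw,
#'   higher-predicts-event scale), `auc_oriented`, `selected`, `note`.
#' @export
univariable_select <- function(train, markers, outcome, positive = NULL,
                               p_max = 0.05, auc_min = 0.65,
                               orient = TRUE) {
  check_columns(train, c(markers, outcome), "training data")
  y <- coerce_binary(train[[outcome]], positive)
  if (sum(y == 1L, na.rm = TRUE) == 0L || sum(y == 0L, na.rm = TRUE) == 0L) {
    abort("Training data must contain both classes.")
  }
  purrr::map_dfr(markers, function(m) {
    x <- train[[m]]
    keep <- !is.na(x) & !is.na(y)
    fit <- tryCatch(
      withCallingHandlers(
        glm(y[keep] ~ x[keep], family = binomial()),
        warning = function(w) {
          if (grepl("converge|fitted probabilities", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }),
      error = function(e) NULL)
    converged <- !is.null(fit) && isTRUE(fit$converged) &&
      !any(is.na(coef(fit)))
    if (!converged) {
      return(tibble::tibble(marker = m, estimate = NA_real_,
                            p_value = NA_real_, auc = NA_real_,
                            auc_oriented = NA_real_, selected = FALSE,
                            note = "fit did not converge; excluded"))
    }
    sm <- summary(fit)$coefficients
    a <- auc_mw(x[keep], y[keep])
    a_gate <- if (orient) max(a, 1 - a) else a
    tibble::tibble(marker = m,
                   estimate = sm[2, "Estimate"],
                   p_value = sm[2, "Pr(>|z|)"],
                   auc = a,
                   auc_oriented = max(a, 1 - a),
                   selected = sm[2, "Pr(>|z|)"] < p_max & a_gate > auc_min,
                   note = NA_character_)
  })
}

# Ridge-penalised logistic log-likelihood fit (penalty on non-intercept
# coefficients only), used when the unpenalised ML fit separates or is
# collinear. Direct Newton iterations on the penalised objective.
ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 100L,
                           tol = 1e-10) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  for (i in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Xd, y - mu)) - drop(pen %*% beta)
    hess <- crossprod(Xd * w, Xd) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  setNames(drop(beta), colnames(Xd))
}

#' Fit the multivariable panel classifier
#'
#' Maximum-likelihood multivariable logistic regression of the outcome on
#' the selected markers. Perfect separation or collinear/duplicated marker
#' columns trigger a small ridge-penalised fallback fit, flagged on the
#' returned model rather than failing, since bootstrap replicates of small
#' cohorts frequently separate.
#'
#' @inheritParams univariable_select
#' @param ridge_lambda Penalty used by the fallback fit (default 1e-3).
#' @return Object of class `panel_classifier`: markers, named coefficient
#'   vector (log-odds scale, intercept first), `penalized` flag, the
#'   underlying `glm` fit when unpenalised, and training metadata.
#' @export
fit_panel_classifier <- function(train, markers, outcome, positive = NULL,
                                 ridge_lambda = 1e-3) {
  check_columns(train, c(markers, outcome), "training data")
  if (length(markers) < 1L) abort("Need at least one marker.")
  y <- coerce_binary(train[[outcome]], positive)
  X <- as.matrix(train[markers])
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  const <- markers[apply(X, 2, function(col) var(col) == 0)]
  if (length(const)) {
    abort(paste("Constant marker column(s):", paste(const, collapse = ", ")))
  }
  collinear <- qr(cbind(1, X))$rank < ncol(X) + 1L
  separated <- FALSE
  fit <- NULL
  if (!collinear) {
    fit <- withCallingHandlers(
      glm(y ~ X, family = binomial()),
      warning = function(w) {
        msg <- conditionMessage(w)
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  msg)) {
          separated <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
  }
  penalized <- collinear || separated || is.null(fit) ||
    !isTRUE(fit$converged) || any(is.na(coef(fit)))
  if (penalized) {
    beta <- ridge_logistic(X, y, lambda = ridge_lambda)
    names(beta) <- c("(Intercept)", markers)
    fit <- NULL
  } else {
    beta <- setNames(coef(fit), c("(Intercept)", markers))
  }
  structure(list(
    markers = markers,
    coefficients = beta,
    penalized = penalized,
    reason = if (collinear) "collinear" else if (separated) "separated"
             else NA_character_,
    fit = fit,
    n = length(y),
    n_pos = sum(y)),
    class = "panel_classifier")
}

#' Construct a panel classifier from known coefficients
#'
#' Builds a scoring-ready `panel_classifier` directly from a coefficient
#' vector, e.g. one read back from a serialised model file.
#'
#' @param coefficients Named numeric vector; first element (or the element
#'   named `"(Intercept)"`) is the intercept, the rest are marker
#'   coefficients named by marker column.
#' @param threshold Optional decision threshold on the 0-100 score scale.
#' @return A `panel_classifier` object.
#' @export
panel_classifier <- function(coefficients, threshold = NULL) {
  nm <- names(coefficients)
  if (is.null(nm)) abort("`coefficients` must be named.")
  int_i <- if ("(Intercept)" %in% nm) match("(Intercept)", nm) else 1L
  structure(list(
    markers = nm[-int_i],
    coefficients = c(`(Intercept)` = unname(coefficients[int_i]),
                     coefficients[-int_i]),
    penalized = FALSE, reason = NA_character_, fit = NULL,
    n = NA_integer_, n_pos = NA_integer_,
    threshold = threshold),
    class = "panel_classifier")
}

#' @export
print.panel_classifier <- function(x, ...) {
  cat("Panel classifier (", length(x$markers), " markers",
      if (isTRUE(x$penalized)) ", ridge-penalised" else "", ")\n", sep = "")
  print(round(x$coefficients, 4))
  if (!is.null(x$threshold)) {
    cat("Decision threshold (0-100 score):", x$threshold, "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.panel_classifier <- function(x, ...) {
  if (!is.null(x$fit)) {
    sm <- summary(x$fit)$coefficients
    tibble::tibble(term = c("(Intercept)", x$markers),
                   estimate = sm[, "Estimate"],
                   std_error = sm[, "Std. Error"],
                   statistic = sm[, "z value"],
                   p_value = sm[, "Pr(>|z|)"])
  } else {
    tibble::tibble(term = names(x$coefficients),
                   estimate = unname(x$coefficients),
                   std_error = NA_real_, statistic = NA_real_,
                   p_value = NA_real_)
  }
}

#' @exportS3Method generics::glance
glance.panel_classifier <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_pos = x$n_pos, n_markers = length(x$markers),
    penalized = x$penalized,
    deviance = if (!is.null(x$fit)) x$fit$deviance else NA_real_,
    aic = if (!is.null(x$fit)) x$fit$aic else NA_real_,
    threshold = x$threshold %||% NA_real_)
}

#' Score patients on the 0-100 classifier scale
#'
#' The classifier score is the predicted event probability times 100, so
#' it is bounded in `[0, 100]` and monotone in the linear predictor; a
#' linear predictor of zero scores 50. Patients missing any model marker
#' receive `NA`.
#'
#' @param model A `panel_classifier`.
#' @param data Tibble containing the model's marker columns.
#' @return `data` with a `score` column appended.
#' @export
score_patients <- function(model, data) {
  check_columns(data, model$markers, "scoring data")
  X <- as.matrix(data[model$markers])
  beta <- model$coefficients
  lp <- drop(beta[1L] + X %*% beta[-1L])
  dplyr::mutate(tibble::as_tibble(data), score = 100 * plogis(lp))
}

#' Classification metrics at a fixed threshold
#'
#' Two-by-two table metrics with the rule "score at or above the threshold
#' predicts the event".
#'
#' @param scores Numeric scores.
#' @param labels Binary outcome (see [marker_auc()]).
#' @param threshold Finite decision threshold.
#' @param positive Positive-class label.
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_at_threshold <- function(scores, labels, threshold,
                                  positive = NULL) {
  if (!is.finite(threshold)) abort("`threshold` must be finite.")
  y <- coerce_binary(labels, positive)
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  if (length(scores) == 0L) abort("No complete score/label pairs.")
  pred <- scores >= threshold
  tp <- sum(pred & y == 1L); fp <- sum(pred & y == 0L)
  tn <- sum(!pred & y == 0L); fn <- sum(!pred & y == 1L)
  tibble::tibble(
    threshold = threshold,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Bootstrapped constrained decision threshold for classifier scores
#'
#' The point threshold is found on the full data by the same constrained
#' search as [constrained_cutpoint()] (maximise sensitivity subject to NPV
#' and specificity floors); the confidence interval is the percentile
#' interval of per-replicate optimal thresholds over class-stratified
#' bootstrap resamples of the scores. To re-fit the logistic model inside
#' each replicate rather than re-thresholding fixed scores, use
#' [train_classifier()] with `refit = TRUE`.
#'
#' @inheritParams evaluate_at_threshold
#' @param min_npv,min_spec Constraint floors (defaults 0.90 and 0.35, the
#'   panel-classifier constraints for the metastasis endpoint).
#' @inheritParams constrained_cutpoint
#' @return One-row tibble of class `threshold_result` with the
#'   [constrained_cutpoint()] columns (`cutpoint` renamed `threshold`).
#' @export
bootstrap_threshold <- function(scores, labels, positive = NULL,
                                min_npv = 0.90, min_spec = 0.35,
                                strict = FALSE, B = 1000,
                                conf_level = 0.95, seed = NULL) {
  res <- constrained_cutpoint(scores, labels, positive = positive,
                              min_npv = min_npv, min_spec = min_spec,
                              direction = "high_risk", strict = strict,
                              B = B, conf_level = conf_level, seed = seed)
  out <- dplyr::rename(tibble::as_tibble(res), threshold = "cutpoint")
  class(out) <- c("threshold_result", class(out))
  out
}

#' Train the full panel classifier with its decision threshold
#'
#' Orchestrates the training protocol: univariable selection, the
#' multivariable logistic fit, 0-100 scoring, and the constrained
#' threshold. With `refit = TRUE` (default) each bootstrap replicate
#' resamples the training cohort, re-fits the logistic model, re-scores
#' and re-thresholds, so the threshold interval reflects model-fitting
#' variability; `refit = FALSE` re-thresholds fixed scores only.
#'
#' @inheritParams univariable_select
#' @inheritParams bootstrap_threshold
#' @param refit Re-fit the logistic model inside each bootstrap replicate?
#' @param seed Integer seed driving selection-independent bootstrap draws.
#' @return A `panel_classifier` with extra fields: `selection` (the
#'   univariable table), `threshold`, `threshold_ci`, `train_metrics`,
#'   `threshold_feasible`, `B`, `seed`.
#' @export
train_classifier <- function(train, markers, outcome, positive = NULL,
                             p_max = 0.05, auc_min = 0.65,
                             min_npv = 0.90, min_spec = 0.35,
                             strict = FALSE, B = 1000, refit = TRUE,
                             seed = NULL) {
  sel <- univariable_select(train, markers, outcome, positive = positive,
                            p_max = p_max, auc_min = auc_min)
  chosen <- sel$marker[sel$selected]
  if (length(chosen) == 0L) {
    abort("No marker passed univariable selection.")
  }
  model <- fit_panel_classifier(train, chosen, outcome, positive = positive)
  scored <- score_patients(model, train)
  y <- coerce_binary(train[[outcome]], positive)
  point <- bootstrap_threshold(scored$score, y, min_npv = min_npv,
                               min_spec = min_spec, strict = strict,
                               B = if (refit) 0L else B, seed = seed)
  ci <- c(point$ci_low, point$ci_high)
  if (refit && isTRUE(point$feasible)) {
    boots <- with_seed_if(seed, {
      vapply(seq_len(B), function(i) {
        idx <- boot_idx_stratified(y)
        bm <- tryCatch(
          fit_panel_classifier(train[idx, , drop = FALSE], chosen, outcome,
                               positive = positive),
          error = function(e) NULL)
        if (is.null(bm)) return(NA_real_)
        bs <- score_patients(bm, train[idx, , drop = FALSE])$score
        sel_b <- select_cutpoint(cutpoint_scan(bs, y[idx]),
                                 min_npv, min_spec, strict)
        if (is.null(sel_b)) NA_real_ else sel_b$cutpoint
      }, numeric(1))
    })
    ci <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  model$selection <- sel
  model$threshold <- point$threshold
  model$threshold_ci <- ci
  model$threshold_feasible <- point$feasible
  model$train_metrics <- point
  model$B <- B
  model$seed <- seed
  model
}

#' Likelihood-ratio comparison of nested models
#'
#' Twice the log-likelihood difference between an augmented model and the
#' base model it nests, on a chi-square reference with degrees of freedom
#' equal to the number of added parameters. Used to test whether a protein
#' panel adds predictive value over standard-of-care covariates.
#'
#' @param base,augmented Fitted model objects with `logLik` methods (e.g.
#'   `glm`), fitted to the same observations, with the base model's terms
#'   a subset of the augmented model's.
#' @return One-row tibble: `chi_squared`, `df`, `p_value`.
#' @export
compare_models_lrt <- function(base, augmented) {
  ll0 <- logLik(base); ll1 <- logLik(augmented)
  n0 <- attr(ll0, "nobs"); n1 <- attr(ll1, "nobs")
  if (!isTRUE(all.equal(n0, n1))) {
    abort("Models were fitted to different numbers of observations.")
  }
  df <- attr(ll1, "df") - attr(ll0, "df")
  if (df < 0) abort("`augmented` has fewer parameters than `base`; models are not nested in that order.")
  t0 <- tryCatch(attr(stats::terms(base), "term.labels"),
                 error = function(e) NULL)
  t1 <- tryCatch(attr(stats::terms(augmented), "term.labels"),
                 error = function(e) NULL)
  if (!is.null(t0) && !is.null(t1) && !all(t0 %in% t1)) {
    abort("Base-model terms are not a subset of the augmented model; not nested.")
  }
  chi2 <- max(0, 2 * (as.numeric(ll1) - as.numeric(ll0)))
  tibble::tibble(chi_squared = chi2, df = df,
                 p_value = if (df == 0) 1 else
                   pchisq(chi2, df, lower.tail = FALSE))
}

#' Cox proportional-hazards assessment of the classifier
#'
#' Fits a multivariable Cox model for a survival endpoint as a function of
#' the panel classifier plus one of two standard-of-care covariate sets:
#' `"biopsy"` (age, race, clinical risk stratum) or `"pathology"`
#' (pathological T stage, top grade group vs the rest, surgical margin).
#' The classifier enters either dichotomised at its decision threshold or
#' as a continuous 0-100 score. The proportional-hazards assumption is
#' checked per covariate by the scaled-Schoenfeld-residual trend test and
#' reported, not enforced.
#'
#' @param data Tibble with survival columns, SOC covariates and a `score`
#'   column.
#' @param time,event Column names of the follow-up time and event
#'   indicator.
#' @param soc `"biopsy"` or `"pathology"`.
#' @param classifier `"dichotomous"` (requires `threshold`) or
#'   `"continuous"`.
#' @param threshold Decision threshold for the dichotomous form.
#' @param score_col Name of the score column (default `"score"`).
#' @return List of class `cox_panel_fit`: `hr_table` (term, HR, CI, p),
#'   `ph_test` (per-covariate PH p-values), `fit` (the `coxph` object),
#'   `dropped` (no-variation covariates removed).
#' @export
cox_classifier <- function(data, time, event,
                           soc = c("biopsy", "pathology"),
                           classifier = c("dichotomous", "continuous"),
                           threshold = NULL, score_col = "score") {
  soc <- match.arg(soc)
  classifier <- match.arg(classifier)
  covs <- if (soc == "biopsy") c("age_at_dx", "race", "nccn") else
    c("path_t", "gg_top", "margin")
  if (soc == "pathology" && !"gg_top" %in% names(data) &&
        "grade_group" %in% names(data)) {
    data$gg_top <- factor(data$grade_group == 5L,
                          levels = c(FALSE, TRUE),
                          labels = c("GG1-4", "GG5"))
  }
  check_columns(data, c(time, event, covs, score_col), "survival data")
  if (classifier == "dichotomous") {
    if (is.null(threshold)) abort("Dichotomous form needs a `threshold`.")
    data$classifier <- factor(data[[score_col]] >= threshold,
                              levels = c(FALSE, TRUE),
                              labels = c("low", "high"))
  } else {
    data$classifier <- data[[score_col]]
  }
  keep <- complete.cases(data[c(time, event, covs, "classifier")])
  data <- data[keep, , drop = FALSE]
  dropped <- covs[vapply(covs, function(v) {
    dplyr::n_distinct(data[[v]]) < 2L
  }, logical(1))]
  if ("classifier" %in% names(data) &&
        dplyr::n_distinct(data$classifier) < 2L) {
    dropped <- c(dropped, "classifier")
  }
  use <- setdiff(c(covs, "classifier"), dropped)
  if (length(dropped)) {
    warn(paste("Dropped covariate(s) with no variation:",
               paste(dropped, collapse = ", ")))
  }
  if (!length(use)) abort("No covariate varies; cannot fit.")
  fml <- as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ",
                           paste(use, collapse = " + ")))
  fit <- survival::coxph(fml, data = data)
  sm <- summary(fit)
  hr <- tibble::tibble(
    term = rownames(sm$coefficients),
    hr = sm$conf.int[, "exp(coef)"],
    ci_low = sm$conf.int[, 3], ci_high = sm$conf.int[, 4],
    p_value = sm$coefficients[, "Pr(>|z|)"])
  ph <- tryCatch({
    z <- survival::cox.zph(fit)
    tibble::tibble(term = rownames(z$table),
                   chi_squared = z$table[, "chisq"],
                   df = z$table[, "df"],
                   p_value = z$table[, "p"])
  }, error = function(e) tibble::tibble(term = character(),
                                        chi_squared = double(),
                                        df = double(), p_value = double()))
  structure(list(hr_table = hr, ph_test = ph, fit = fit,
                 dropped = dropped, n = sm$n, n_event = sm$nevent),
            class = "cox_panel_fit")
}

#' @export
print.cox_panel_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (n =", x$n, ", events =", x$n_event,
      ")\n")
  print(dplyr::mutate(x$hr_table,
                      dplyr::across(dplyr::where(is.numeric), ~round(., 3))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cox_panel_fit <- function(x, ...) x$hr_table

#' @exportS3Method generics::glance
glance.cox_panel_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event,
                 ph_global_ok = all(x$ph_test$p_value >= 0.05,
                                    na.rm = TRUE),
                 concordance = unname(summary(x$fit)$concordance[1]))
}

#' Serialise a trained classifier to JSON
#'
#' Writes markers, coefficients, the 0-100 scaling rule, the decision
#' threshold and training metadata; [read_classifier_json()] restores a
#' scoring-ready model.
#'
#' @param model A `panel_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier_json <- function(model, path) {
  obj <- list(
    markers = model$markers,
    coefficients = as.list(model$coefficients),
    scaling = "predicted_probability_x_100",
    threshold = model$threshold %||% NA,
    threshold_ci = model$threshold_ci %||% c(NA, NA),
    penalized = model$penalized,
    n_train = model$n, n_pos_train = model$n_pos,
    B = model$B %||% NA, seed = model$seed %||% NA)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(obj$coefficients)
  m <- panel_classifier(beta,
                        threshold = if (is.na(obj$threshold)) NULL else
                          obj$threshold)
  m$threshold_ci <- obj$threshold_ci
  m
}
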