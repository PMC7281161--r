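#' Descriptive cohort summary with group-difference tests
#'
#' Tests each clinical variable for distributional differences across
#' outcome groups: continuous variables with one-way ANOVA and, in
#' parallel, the Kruskal-Wallis rank test; categorical variables with the
#' Pearson chi-square test (no continuity correction), switching to
#' Fisher's exact test whenever any expected cell count falls below 5.
#' Complete cases per variable; the number excluded is reported.
#'
#' @param cohort Data frame of patient records.
#' @param group Name of the grouping column (default `"outcome"`).
#' @param vars Variables to summarise; defaults to every column except the
#'   grouping column and obvious identifiers/time columns.
#' @return Tibble with one row per variable: `variable`, `type`, `test`,
#'   `statistic`, `df`, `p_value` (for continuous variables the ANOVA
#'   entries, with `p_kruskal` alongside), `n_used`, `n_missing`, `note`.
#' @export
summarize_cohort <- function(cohort, group = "outcome", vars = NULL) {
  check_columns(cohort, group, "cohort")
  g_all <- cohort[[group]]
  if (dplyr::n_distinct(g_all[!is.na(g_all)]) < 2L) {
    abort("Need at least two outcome groups to test.")
  }
  if (is.null(vars)) {
    drop <- c(group, "patient_id", "sample_id", "time_to_bcr", "time_to_dm")
    vars <- setdiff(names(cohort), drop)
  }
  purrr::map_dfr(vars, function(v) {
    x <- cohort[[v]]
    keep <- !is.na(x) & !is.na(g_all)
    x <- x[keep]
    g <- factor(g_all[keep])
    base <- tibble::tibble(variable = v, n_used = sum(keep),
                           n_missing = sum(!keep))
    if (dplyr::n_distinct(x) < 2L) {
      return(dplyr::bind_cols(base, tibble::tibble(
        type = if (is.numeric(x)) "continuous" else "categorical",
        test = NA_character_, statistic = NA_real_, df = NA_real_,
        p_value = NA_real_, p_kruskal = NA_real_,
        note = "single distinct value; test skipped")))
    }
    if (is.numeric(x)) {
      a <- summary(aov(x ~ g))[[1]]
      kw <- kruskal.test(x, g)
      dplyr::bind_cols(base, tibble::tibble(
        type = "continuous", test = "anova",
        statistic = a[["F value"]][1], df = a[["Df"]][1],
        p_value = a[["Pr(>F)"]][1],
        p_kruskal = kw$p.value, note = NA_character_))
    } else {
      tab <- table(factor(x), g)
      cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
      if (any(cs$expected < 5)) {
        ft <- fisher.test(tab, simulate.p.value = prod(dim(tab)) > 10,
                          B = 1e5)
        dplyr::bind_cols(base, tibble::tibble(
          type = "categorical", test = "fisher",
          statistic = NA_real_, df = NA_real_, p_value = ft$p.value,
          p_kruskal = NA_real_,
          note = "expected count < 5; Fisher exact used"))
      } else {
        dplyr::bind_cols(base, tibble::tibble(
          type = "categorical", test = "chisq",
          statistic = unname(cs$statistic), df = unname(cs$parameter),
          p_value = cs$p.value, p_kruskal = NA_real_,
          note = NA_character_))
      }
    }
  })
}

# Mann-Whitney AUC with tie correction: mean rank of positives, rescaled.
auc_mw <- function(values, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(values)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified bootstrap indices: resample within classes so every replicate
# keeps both classes.
boot_idx_stratified <- function(labels) {
  i_pos <- which(labels == 1L)
  i_neg <- which(labels == 0L)
  c(i_pos[sample.int(length(i_pos), length(i_pos), replace = TRUE)],
    i_neg[sample.int(length(i_neg), length(i_neg), replace = TRUE)])
}

coerce_binary <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("Numeric labels must be 0/1.")
    return(as.integer(labels))
  }
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L) abort("Labels must have exactly two classes.")
  pos <- positive %||% lv[2L]
  if (!pos %in% lv) abort(sprintf("Positive class '%s' not found.", pos))
  as.integer(as.character(labels) == pos)
}

#' Marker AUC with bootstrap confidence interval
#'
#' The area under the ROC curve computed as the tie-corrected Mann-Whitney
#' statistic divided by `n_pos * n_neg` (ties count one half). The
#' confidence interval is a nonparametric percentile bootstrap, stratified
#' by class; the p-value tests AUC = 0.5 via the normal-approximation
#' Mann-Whitney test.
#'
#' @param values Numeric marker values.
#' @param labels Binary outcome (logical, 0/1, or two-level factor with
#'   `positive` naming the event class).
#' @param positive Positive-class label for factor/character `labels`.
#' @param B Bootstrap replicates (default 1000).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Optional integer seed; the global RNG stream is left
#'   untouched.
#' @return One-row tibble: `auc`, `ci_low`, `ci_high`, `p_value`, `n_pos`,
#'   `n_neg`.
#' @export
marker_auc <- function(values, labels, positive = NULL, B = 1000,
                       conf_level = 0.95, seed = NULL) {
  y <- coerce_binary(labels, positive)
  keep <- !is.na(values) & !is.na(y)
  values <- values[keep]; y <- y[keep]
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    abort("Both classes must be present to compute an AUC.")
  }
  est <- auc_mw(values, y)
  p <- suppressWarnings(
    wilcox.test(values[y == 1L], values[y == 0L],
                exact = FALSE, correct = FALSE)$p.value)
  ci <- with_seed_if(seed, {
    reps <- vapply(seq_len(B), function(i) {
      idx <- boot_idx_stratified(y)
      auc_mw(values[idx], y[idx])
    }, numeric(1))
    quantile(reps, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
             names = FALSE, type = 7)
  })
  tibble::tibble(auc = est, ci_low = ci[1], ci_high = ci[2], p_value = p,
                 n_pos = sum(y == 1L), n_neg = sum(y == 0L))
}

#' Evaluate a set of markers against an endpoint
#'
#' Data-frame wrapper around [marker_auc()]: one AUC row per marker column.
#'
#' @param data Cohort tibble holding marker columns and the outcome.
#' @param markers Character vector of marker column names.
#' @param outcome Outcome column name.
#' @inheritParams marker_auc
#' @return Tibble with `marker` plus the [marker_auc()] columns, sorted by
#'   decreasing AUC.
#' @export
evaluate_markers <- function(data, markers, outcome, positive = NULL,
                             B = 1000, conf_level = 0.95, seed = NULL) {
  check_columns(data, c(markers, outcome), "marker data")
  res <- purrr::imap_dfr(
    setNames(markers, markers),
    function(m, nm) {
      marker_auc(data[[m]], data[[outcome]], positive = positive, B = B,
                 conf_level = conf_level,
                 seed = if (is.null(seed)) NULL else
                   seed + match(nm, markers))
    }, .id = "marker")
  dplyr::arrange(res, dplyr::desc(.data$auc))
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise type I error rate, in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`; e.g. testing 16 markers at 0.05 gives 0.003125.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 16) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  if (!is.numeric(m) || m < 1) abort("`m` must be >= 1.")
  alpha / m
}

# Classification metrics at every candidate threshold (rule: value >= cut
# predicts positive). Candidates are midpoints between consecutive sorted
# unique values plus -Inf/+Inf, which exhausts all distinct 2x2 tables.
cutpoint_scan <- function(values, labels) {
  v_sort <- sort(unique(values))
  cand <- if (length(v_sort) > 1L) {
    c(-Inf, (v_sort[-1] + v_sort[-length(v_sort)]) / 2, Inf)
  } else c(-Inf, Inf)
  o <- order(values)
  v <- values[o]; y <- labels[o]
  n_pos <- sum(y); n_neg <- length(y) - n_pos
  cum_pos <- c(0, cumsum(y))
  cum_neg <- c(0, cumsum(1 - y))
  k <- findInterval(cand, v)        # values strictly below each candidate
  fn <- cum_pos[k + 1]; tn <- cum_neg[k + 1]
  tp <- n_pos - fn; fp <- n_neg - tn
  tibble::tibble(
    cutpoint = cand, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / n_pos,
    specificity = tn / n_neg,
    ppv = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    npv = ifelse(tn + fn > 0, tn / (tn + fn), NA_real_)
  )
}

# Feasible-set selection: max sensitivity, ties to higher specificity, then
# larger threshold. Constraints evaluated as ">= " (the stated "at least"),
# or strictly ">" when strict = TRUE. An undefined NPV/PPV (empty
# prediction arm) never satisfies a positive constraint.
select_cutpoint <- function(scan, min_npv, min_spec, strict = FALSE) {
  ok_npv <- if (strict) scan$npv > min_npv else scan$npv >= min_npv
  ok_spec <- if (strict) scan$specificity > min_spec else
    scan$specificity >= min_spec
  feas <- which(!is.na(ok_npv) & ok_npv & ok_spec)
  if (length(feas) == 0L) return(NULL)
  f <- scan[feas, ]
  f <- f[order(-f$sensitivity, -f$specificity, -f$cutpoint), ]
  f[1L, ]
}

#' Constrained optimal cut-point for a single marker
#'
#' Scans every achievable threshold (midpoints between consecutive sorted
#' unique values plus the two infinite sentinels) and, among those meeting
#' the negative-predictive-value and specificity constraints, returns the
#' one with the highest sensitivity (ties broken by higher specificity,
#' then by larger threshold). The bootstrap confidence interval is the
#' percentile interval of the per-replicate optimal cut-points over
#' class-stratified resamples.
#'
#' Markers protective at high values (AUC below 0.5 when higher-is-risk)
#' are flipped internally when `direction = "auto"`; the reported cut-point
#' is on the original scale with `direction = "low_risk"` recorded.
#'
#' @inheritParams marker_auc
#' @param min_npv,min_spec Constraint floors in `[0, 1]` (defaults 0.80 and
#'   0.40, the single-marker screening constraints for the metastasis
#'   endpoint; the recurrence endpoint conventionally uses 0.70/0.30).
#' @param direction `"auto"`, `"high_risk"` (values at or above the cut
#'   predict the event) or `"low_risk"` (values at or below predict it).
#' @param strict Evaluate constraints strictly (`>`)? Default `FALSE`
#'   (`>=`).
#' @return One-row tibble of class `cutpoint_result`: `cutpoint`,
#'   `direction`, `sensitivity`, `specificity`, `ppv`, `npv`, `ci_low`,
#'   `ci_high`, `feasible`, `n_boot_feasible`. Infeasible searches return
#'   `feasible = FALSE` with `NA` metrics.
#' @export
constrained_cutpoint <- function(values, labels, positive = NULL,
                                 min_npv = 0.80, min_spec = 0.40,
                                 direction = c("auto", "high_risk",
                                               "low_risk"),
                                 strict = FALSE, B = 1000,
                                 conf_level = 0.95, seed = NULL) {
  direction <- match.arg(direction)
  if (min_npv < 0 || min_npv > 1 || min_spec < 0 || min_spec > 1) {
    abort("Constraints must lie in [0, 1].")
  }
  y <- coerce_binary(labels, positive)
  keep <- !is.na(values) & !is.na(y)
  values <- values[keep]; y <- y[keep]
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    abort("Both classes must be present.")
  }
  if (direction == "auto") {
    direction <- if (auc_mw(values, y) < 0.5) "low_risk" else "high_risk"
  }
  flip <- direction == "low_risk"
  v <- if (flip) -values else values

  best <- select_cutpoint(cutpoint_scan(v, y), min_npv, min_spec, strict)
  infeasible <- tibble::tibble(
    cutpoint = NA_real_, direction = direction,
    sensitivity = NA_real_, specificity = NA_real_,
    ppv = NA_real_, npv = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_,
    feasible = FALSE, n_boot_feasible = NA_integer_)
  if (is.null(best)) {
    class(infeasible) <- c("cutpoint_result", class(infeasible))
    return(infeasible)
  }
  boots <- if (B > 0) {
    with_seed_if(seed, {
      vapply(seq_len(B), function(i) {
        idx <- boot_idx_stratified(y)
        sel <- select_cutpoint(cutpoint_scan(v[idx], y[idx]),
                               min_npv, min_spec, strict)
        if (is.null(sel)) NA_real_ else sel$cutpoint
      }, numeric(1))
    })
  } else numeric(0)
  ci <- if (any(!is.na(boots))) {
    quantile(boots, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
             na.rm = TRUE, names = FALSE, type = 7)
  } else c(NA_real_, NA_real_)
  if (flip) ci <- rev(-ci)
  out <- tibble::tibble(
    cutpoint = if (flip) -best$cutpoint else best$cutpoint,
    direction = direction,
    sensitivity = best$sensitivity, specificity = best$specificity,
    ppv = best$ppv, npv = best$npv,
    ci_low = ci[1], ci_high = ci[2],
    feasible = TRUE, n_boot_feasible = sum(!is.na(boots)))
  class(out) <- c("cutpoint_result", class(out))
  out
}

#' Constrained cut-points for several markers
#'
#' @inheritParams evaluate_markers
#' @inheritParams constrained_cutpoint
#' @return Tibble with `marker` plus the [constrained_cutpoint()] columns.
#' @export
find_cutpoints <- function(data, markers, outcome, positive = NULL,
                           min_npv = 0.80, min_spec = 0.40,
                           direction = "auto", strict = FALSE, B = 1000,
                           conf_level = 0.95, seed = NULL) {
  check_columns(data, c(markers, outcome), "marker data")
  purrr::imap_dfr(
    setNames(markers, markers),
    function(m, nm) {
      constrained_cutpoint(data[[m]], data[[outcome]], positive = positive,
                           min_npv = min_npv, min_spec = min_spec,
                           direction = direction, strict = strict, B = B,
                           conf_level = conf_level,
                           seed = if (is.null(seed)) NULL else
                             seed + match(nm, markers))
    }, .id = "marker")
}

#' Principal-component screen of a marker panel
#'
#' Eigendecomposition of the marker correlation matrix; components with an
#' eigenvalue above 1 (the Kaiser criterion) are retained as panel
#' candidates and their loadings reported.
#'
#' @param data Tibble holding the marker columns.
#' @param markers Marker column names; default: all numeric columns.
#' @return List of class `panel_pca`: `eigenvalues` (tibble `component`,
#'   `eigenvalue`, `prop_var`, `retained`), `loadings` (markers x
#'   components matrix), `n_retained`, `markers`.
#' @export
pca_panel_screen <- function(data, markers = NULL) {
  if (is.null(markers)) {
    markers <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  check_columns(data, markers, "marker data")
  X <- as.matrix(data[markers])
  X <- X[complete.cases(X), , drop = FALSE]
  if (ncol(X) < 2L) abort("Need at least two markers.")
  if (nrow(X) < 3L) abort("Need at least three complete samples.")
  const <- markers[apply(X, 2, function(col) var(col) == 0)]
  if (length(const)) {
    abort(paste("Constant marker column(s):", paste(const, collapse = ", ")))
  }
  ev <- eigen(stats::cor(X), symmetric = TRUE)
  vals <- ev$values
  load <- ev$vectors
  dimnames(load) <- list(markers, paste0("PC", seq_along(vals)))
  out <- list(
    eigenvalues = tibble::tibble(
      component = paste0("PC", seq_along(vals)),
      eigenvalue = vals,
      prop_var = vals / length(vals),
      retained = vals > 1),
    loadings = load,
    n_retained = sum(vals > 1),
    markers = markers)
  class(out) <- "panel_pca"
  out
}

#' @export
print.panel_pca <- function(x, ...) {
  cat("Principal-component marker screen (", length(x$markers),
      " markers)\n", sep = "")
  cat("Components with eigenvalue > 1:", x$n_retained, "\n")
  print(x$eigenvalues, n = 5)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.panel_pca <- function(x, ...) x$eigenvalues

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator; censored subjects leave the risk set without
#' contributing an event.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicator (1 = event, 0 = censored).
#' @return Tibble of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `estimate`, `std_error`, `ci_low`, `ci_high`.
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0, na.rm = TRUE)) abort("Times must be non-negative.")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, estimate = fit$surv,
    std_error = fit$std.err, ci_low = fit$lower, ci_high = fit$upper)
  class(out) <- c("km_curve", class(out))
  out
}

#' Log-rank test across groups
#'
#' @inheritParams km_estimate
#' @param groups Group labels; at least two non-empty groups.
#' @return One-row tibble: `chi_squared`, `df`, `p_value`, `n`.
#' @export
logrank_test <- function(times, events, groups) {
  if (any(times < 0, na.rm = TRUE)) abort("Times must be non-negative.")
  g <- factor(groups)
  if (nlevels(droplevels(g)) < 2L) {
    abort("Need at least two non-empty groups.")
  }
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- length(sd_fit$n) - 1L
  tibble::tibble(chi_squared = sd_fit$chisq, df = df,
                 p_value = pchisq(sd_fit$chisq, df, lower.tail = FALSE),
                 n = sum(sd_fit$n))
}
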