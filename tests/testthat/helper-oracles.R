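# Independent oracles used across the suite. These are deliberately naive
# (exhaustive counting, closed forms, hand-rolled product limits) and must
# stay independent of the package implementations they check.

# AUC by exhaustive pairwise concordance counting, half credit for ties.
oracle_auc <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Two-parameter OLS closed form.
oracle_ols <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# Brute-force constrained cut-point search: every midpoint candidate plus
# sentinels, direct 2x2 counting, max sensitivity with ties to higher
# specificity then larger cut. Returns NULL when infeasible.
oracle_cutpoint <- function(values, labels, min_npv, min_spec,
                            strict = FALSE) {
  u <- sort(unique(values))
  cand <- if (length(u) > 1) c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
          else c(-Inf, Inf)
  best <- NULL
  for (cut in cand) {
    pred <- values >= cut
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    tn <- sum(!pred & labels == 0); fn <- sum(!pred & labels == 1)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    ok <- if (strict) isTRUE(npv > min_npv) && spec > min_spec else
      isTRUE(npv >= min_npv) && spec >= min_spec
    if (!ok) next
    if (is.null(best) || sens > best$sens ||
          (sens == best$sens && spec > best$spec) ||
          (sens == best$sens && spec == best$spec && cut > best$cut)) {
      best <- list(cut = cut, sens = sens, spec = spec, npv = npv,
                   ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
    }
  }
  best
}

# Hand product-limit estimator over unique event times.
oracle_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / at_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# Hand observed-minus-expected two-group log-rank chi-square.
oracle_logrank <- function(times, events, groups) {
  g <- as.integer(factor(groups)) - 1L   # 0/1
  u_t <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in u_t) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  o_minus_e^2 / v
}

# Cohort reproducing the published race x outcome contingency counts
# (AA 55/48/17, CA_other 106/75/36 across nonevent/BCR/metastasis).
make_race_cohort <- function() {
  tibble::tibble(
    race = rep(rep(c("AA", "CA_other"), 3), c(55, 106, 48, 75, 17, 36)),
    outcome = rep(c("nonevent", "bcr", "dm"), c(161, 123, 53)))
}

# Small two-class marker with a planted standardized shift.
make_binary_marker <- function(n_pos, n_neg, d, seed) {
  withr::with_seed(seed, {
    list(values = c(rnorm(n_pos, d), rnorm(n_neg, 0)),
         labels = rep(c(1L, 0L), c(n_pos, n_neg)))
  })
}

# Noiseless calibration table for one peptide from a planted line, with
# S/N rising linearly through `lod` (replicate jitter `cv` on the ratio).
make_calibration <- function(slope, intercept, lod = 12,
                             levels = c(0, 0.6, 3, 12, 60, 300, 1500,
                                        3000, 6000, 12000, 24000, 48000),
                             cv = 0, background = 50, seed = 1,
                             peptide_id = "PEP_A") {
  grid <- expand.grid(spike_conc = levels, replicate = 1:3)
  withr::with_seed(seed, {
    noise <- if (cv == 0) rep(1, nrow(grid)) else
      exp(rnorm(nrow(grid), 0, sqrt(log(1 + cv^2))))
    tibble::tibble(
      peptide_id = peptide_id,
      spike_conc = grid$spike_conc,
      replicate = grid$replicate,
      hl_ratio = (slope * grid$spike_conc + intercept) * noise,
      background_noise = background,
      apex_intensity = background * 3 * grid$spike_conc / lod)
  })
}
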