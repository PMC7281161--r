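#' Default planted marker separations
#'
#' Sixteen prostate-tissue protein markers with the per-endpoint
#' discriminations (AUC scale) reported for the cohort this pipeline was
#' designed around. The planted standardized mean shift for a marker with
#' oriented AUC `a` is `d = sqrt(2) * qnorm(a)` under the equal-variance
#' binormal model, so simulated cohorts reproduce discriminations of the
#' published magnitude. Tissue PSA discriminates metastasis in the
#' protective direction (lower levels in progressors), encoded by
#' `sign_dm = -1`.
#'
#' @return Tibble: `marker`, `auc_dm`, `auc_bcr`, `sign_dm`.
#' @export
default_marker_effects <- function() {
  tibble::tibble(
    marker = c("ANXA2", "CAMKK2", "CCND1", "EGFR", "ERG", "FOLH1", "MMP9",
               "MUC1", "NCOA2", "PSA", "SMAD4", "SPINK1", "SPARC", "TFF3",
               "TGFB1", "VEGFA"),
    auc_dm = c(0.535, 0.591, 0.532, 0.628, 0.543, 0.653, 0.562, 0.570,
               0.637, 0.730, 0.511, 0.486, 0.800, 0.541, 0.788, 0.528),
    auc_bcr = c(0.538, 0.604, 0.624, 0.578, 0.546, 0.627, 0.511, 0.474,
                0.613, 0.529, 0.526, 0.548, 0.695, 0.472, 0.649, 0.601),
    sign_dm = c(1, 1, 1, 1, 1, 1, 1, 1, 1, -1, 1, 1, 1, 1, 1, 1))
}

# Per-group marginal frequencies of the clinical covariates in the study
# cohort (nonevent / BCR / metastasis), used as categorical lookups.
cohort_marginals <- function() {
  list(
    race = list(levels = c("AA", "CA_other"),
                nonevent = c(55, 106), bcr = c(48, 75), dm = c(17, 36)),
    psa_dx = list(levels = c("<10", "10-20", ">20"),
                  nonevent = c(133, 25, 1), bcr = c(90, 25, 9),
                  dm = c(39, 9, 5)),
    clinical_t = list(levels = c("T1-T2a", "T2b-T2c", "T3a-T4"),
                      nonevent = c(134, 22, 1), bcr = c(107, 15, 2),
                      dm = c(33, 15, 5)),
    biopsy_grade = list(levels = c("<=6", "7", "8-10"),
                        nonevent = c(100, 35, 6), bcr = c(68, 41, 10),
                        dm = c(14, 19, 19)),
    nccn = list(levels = c("low", "intermediate", "high"),
                nonevent = c(69, 59, 8), bcr = c(46, 55, 19),
                dm = c(10, 20, 22)),
    path_t = list(levels = c("pT2", "pT3-4"),
                  nonevent = c(119, 41), bcr = c(46, 77), dm = c(9, 39)),
    grade_group = list(levels = c("1", "2", "3", "4", "5"),
                       nonevent = c(18, 77, 2, 54, 9),
                       bcr = c(13, 27, 4, 49, 30),
                       dm = c(0, 1, 0, 21, 27)),
    margin = list(levels = c("neg", "pos"),
                  nonevent = c(126, 33), bcr = c(62, 59), dm = c(21, 27)))
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator with defaults
#' matching the study conditions the pipeline assumes: a 338-patient
#' cohort with outcome mix 161 nonevent / 124 biochemical recurrence (BCR)
#' / 53 distant metastasis (DM); median times to BCR and DM of 1.7 and 6.7
#' years; nonevents censored after at least 120 months of follow-up; the
#' twelve-level calibration series with three injection replicates; and a
#' linear heavy/light SRM response with multiplicative log-normal noise.
#'
#' @param n_patients Cohort size (default 338).
#' @param prevalence Named outcome probabilities (`nonevent`, `bcr`, `dm`);
#'   must sum to 1.
#' @param marker_effects Tibble as [default_marker_effects()].
#' @param median_bcr_months,median_dm_months Exponential event-time
#'   medians (20.4 and 80.4 months).
#' @param followup_range_nonevent Censoring window (months) for nonevents,
#'   default `c(120, 253)`.
#' @param calibration_levels Heavy spike levels, amol/ug.
#' @param n_replicates Injection replicates per level (3).
#' @param c_light_matrix True light-peptide concentration of the pooled
#'   calibration matrix, amol/ug (also the per-marker median study-sample
#'   concentration).
#' @param intercept Calibration intercept (H/L at zero spike).
#' @param noise_cv Multiplicative coefficient of variation of measured
#'   ratios (default 0.10).
#' @param background Chromatographic background level, counts.
#' @param lod_target Planted LOD level: generated S/N equals
#'   `3 * spike / lod_target`, so the S/N = 3 crossing sits exactly there.
#' @param sample_spike Heavy spike added to study samples, amol/ug (300).
#' @param sd_log10 Spread of true log10 concentrations per unit of
#'   standardized marker shift (0.3).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 338,
                       prevalence = c(nonevent = 161, bcr = 124, dm = 53) /
                         338,
                       marker_effects = default_marker_effects(),
                       median_bcr_months = 1.7 * 12,
                       median_dm_months = 6.7 * 12,
                       followup_range_nonevent = c(120, 253),
                       calibration_levels = c(0, 0.6, 3, 12, 60, 300, 1500,
                                              3000, 6000, 12000, 24000,
                                              48000),
                       n_replicates = 3,
                       c_light_matrix = 500,
                       intercept = 0.02,
                       noise_cv = 0.10,
                       background = 50,
                       lod_target = 12,
                       sample_spike = 300,
                       sd_log10 = 0.3) {
  if (abs(sum(prevalence) - 1) > 1e-8) abort("Prevalences must sum to 1.")
  if (!all(c("nonevent", "bcr", "dm") %in% names(prevalence))) {
    abort("`prevalence` needs names nonevent, bcr, dm.")
  }
  if (noise_cv < 0) abort("`noise_cv` must be non-negative.")
  if (is.unsorted(calibration_levels, strictly = TRUE)) {
    abort("`calibration_levels` must be strictly increasing.")
  }
  structure(list(
    n_patients = n_patients, prevalence = prevalence,
    marker_effects = marker_effects,
    median_bcr_months = median_bcr_months,
    median_dm_months = median_dm_months,
    followup_range_nonevent = followup_range_nonevent,
    calibration_levels = calibration_levels,
    n_replicates = n_replicates,
    c_light_matrix = c_light_matrix, intercept = intercept,
    noise_cv = noise_cv, background = background,
    lod_target = lod_target, sample_spike = sample_spike,
    sd_log10 = sd_log10), class = "sim_config")
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Simulate a calibration series
#'
#' Heavy-over-light ratios follow the linear forward model
#' `H/L = spike / c_light + intercept` with multiplicative log-normal
#' noise. The generated S/N rises linearly through the planted LOD level
#' (`S/N = 3 * spike / lod_target`), so the LOD/LOQ rules recover it; the
#' implied LOQ is the lowest level with S/N of at least 10.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return List: `points` (tibble of `peptide_id`, `protein_id`,
#'   `spike_conc`, `replicate`, `hl_ratio`, `apex_intensity`,
#'   `background_noise`, `light_area`, `heavy_area`) and `truth` (planted
#'   slope/intercept/light concentration and limits per peptide).
#' @export
simulate_calibration <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  markers <- config$marker_effects$marker
  slope <- 1 / config$c_light_matrix
  lv <- config$calibration_levels
  loq_implied <- lv[lv > 0][which(3 * lv[lv > 0] / config$lod_target >= 10)[1]]
  grid <- tidyr::expand_grid(
    protein_id = markers,
    spike_conc = lv,
    replicate = seq_len(config$n_replicates)) |>
    dplyr::mutate(peptide_id = paste0("PEP_", .data$protein_id))
  points <- with_seed_if(seed, {
    grid |>
      dplyr::mutate(
        hl_ratio = (slope * .data$spike_conc + config$intercept) *
          lognormal_noise(dplyr::n(), config$noise_cv),
        background_noise = config$background,
        apex_intensity = config$background * 3 * .data$spike_conc /
          config$lod_target,
        light_area = 1e6,
        heavy_area = .data$hl_ratio * 1e6)
  })
  truth <- list(slope = slope, intercept = config$intercept,
                c_light_matrix = config$c_light_matrix,
                lod = config$lod_target, loq = loq_implied)
  list(points = dplyr::select(points, "peptide_id", "protein_id",
                              "spike_conc", "replicate", "hl_ratio",
                              "apex_intensity", "background_noise",
                              "light_area", "heavy_area"),
       truth = truth)
}

draw_categorical <- function(spec, group_counts) {
  # group_counts: named list nonevent/bcr/dm of how many draws per group
  unlist(lapply(names(group_counts), function(g) {
    n <- group_counts[[g]]
    w <- spec[[g]]
    sample(spec$levels, n, replace = TRUE, prob = w / sum(w))
  }))
}

#' Simulate a patient cohort with planted marker effects
#'
#' Outcome classes are drawn at the configured prevalences. Marker values
#' are standardized log-abundances `N(mu_group, 1)` where the nonevent
#' mean is 0 and the event-group means are the planted shifts
#' `d = sqrt(2) * qnorm(AUC)` (signed; see [default_marker_effects()]), so
#' the population DM-vs-nonevent AUC of each marker equals the configured
#' value via `AUC = pnorm(d / sqrt(2))`. Clinical covariates are drawn
#' from per-group marginal frequencies of the reference cohort (a lookup,
#' not a causal model). Event times are exponential with the configured
#' medians; nonevents are censored uniformly inside the configured
#' follow-up window.
#'
#' @inheritParams simulate_calibration
#' @return List: `cohort` (tibble of patient records with marker columns
#'   holding standardized log-abundances) and `truth` (planted shifts and
#'   the latent marker matrix).
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  me <- config$marker_effects
  d_dm <- me$sign_dm * sqrt(2) * qnorm(me$auc_dm)
  d_bcr <- sqrt(2) * qnorm(me$auc_bcr)
  names(d_dm) <- names(d_bcr) <- me$marker
  marg <- cohort_marginals()
  with_seed_if(seed, {
    n <- config$n_patients
    outcome <- sample(c("nonevent", "bcr", "dm"), n, replace = TRUE,
                      prob = config$prevalence[c("nonevent", "bcr", "dm")])
    outcome <- factor(outcome, levels = c("nonevent", "bcr", "dm"))
    ord <- order(outcome)      # group-blocked for the marginal lookups
    outcome <- outcome[ord]
    counts <- as.list(table(outcome))
    Z <- vapply(me$marker, function(m) {
      mu <- c(nonevent = 0, bcr = d_bcr[[m]], dm = d_dm[[m]])
      rnorm(n, mean = mu[as.character(outcome)], sd = 1)
    }, numeric(n))
    age_pars <- list(nonevent = c(59.0, 8.1), bcr = c(59.2, 7.7),
                     dm = c(61.7, 5.9))
    age <- unlist(lapply(names(counts), function(g) {
      rnorm(counts[[g]], age_pars[[g]][1], age_pars[[g]][2])
    }))
    cats <- lapply(marg, draw_categorical, group_counts = counts)
    t_bcr <- t_dm <- rep(NA_real_, n)
    fup <- numeric(n)
    is_ne <- outcome == "nonevent"
    is_bcr <- outcome == "bcr"
    is_dm <- outcome == "dm"
    fup[is_ne] <- runif(sum(is_ne), config$followup_range_nonevent[1],
                        config$followup_range_nonevent[2])
    t_bcr[is_bcr] <- rexp(sum(is_bcr),
                          rate = log(2) / config$median_bcr_months)
    fup[is_bcr] <- t_bcr[is_bcr] + runif(sum(is_bcr), 0, 120)
    t_dm[is_dm] <- rexp(sum(is_dm), rate = log(2) / config$median_dm_months)
    t_bcr[is_dm] <- t_dm[is_dm] * runif(sum(is_dm), 0.2, 0.9)
    fup[is_dm] <- t_dm[is_dm] + runif(sum(is_dm), 0, 60)
    cohort <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      age_at_dx = age,
      race = cats$race, psa_dx = cats$psa_dx,
      clinical_t = cats$clinical_t, biopsy_grade = cats$biopsy_grade,
      nccn = cats$nccn, path_t = cats$path_t,
      grade_group = as.integer(cats$grade_group), margin = cats$margin,
      outcome = as.character(outcome),
      time_to_bcr = t_bcr, time_to_dm = t_dm, followup = fup)
    cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(Z))
    list(cohort = cohort,
         truth = list(d_dm = d_dm, d_bcr = d_bcr, markers = me$marker,
                      latent = Z, config = config))
  })
}

#' Simulate an SRM transition report from cohort ground truth
#'
#' Maps each patient's latent standardized marker value `z` to a true
#' endogenous concentration `c = c_light * 10^(sd_log10 * z)` and pushes
#' it through the planted calibration forward model to a light-over-heavy
#' ratio with multiplicative noise:
#' `L/H = (slope * c + intercept) * c_light / spike * noise`. Running the
#' result through [quantify_samples()] with the planted curves recovers
#' the true concentrations (exactly when `noise_cv = 0`).
#'
#' @param cohort_sim Result of [simulate_cohort()].
#' @param config A [sim_config()]; defaults to the one stored in
#'   `cohort_sim$truth`.
#' @inheritParams simulate_calibration
#' @return List: `report` (transition-report tibble with columns
#'   `peptide_id`, `protein_id`, `sample_id`, `light_area`, `heavy_area`,
#'   `apex_intensity`, `background_noise`, `heavy_spike_amol_per_ug`) and
#'   `truth` (patients x markers matrix of true concentrations, amol/ug).
#' @export
simulate_srm_from_cohort <- function(cohort_sim, config = NULL,
                                     seed = NULL) {
  config <- config %||% cohort_sim$truth$config
  stopifnot(inherits(config, "sim_config"))
  Z <- cohort_sim$truth$latent
  ids <- cohort_sim$cohort$patient_id
  markers <- cohort_sim$truth$markers
  conc <- config$c_light_matrix * 10^(config$sd_log10 * Z)
  dimnames(conc) <- list(ids, markers)
  slope <- 1 / config$c_light_matrix
  long <- tidyr::expand_grid(sample_id = ids, protein_id = markers) |>
    dplyr::mutate(
      peptide_id = paste0("PEP_", .data$protein_id),
      c_true = conc[cbind(.data$sample_id, .data$protein_id)])
  report <- with_seed_if(seed, {
    long |>
      dplyr::mutate(
        lh_ratio = (slope * .data$c_true + config$intercept) *
          config$c_light_matrix / config$sample_spike *
          lognormal_noise(dplyr::n(), config$noise_cv),
        heavy_area = 1e5,
        light_area = .data$lh_ratio * 1e5,
        apex_intensity = config$background * 20,
        background_noise = config$background,
        heavy_spike_amol_per_ug = config$sample_spike)
  })
  list(report = dplyr::select(report, "peptide_id", "protein_id",
                              "sample_id", "light_area", "heavy_area",
                              "apex_intensity", "background_noise",
                              "heavy_spike_amol_per_ug"),
       truth = conc)
}
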