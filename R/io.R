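read_delim_auto <- function(path, col_types) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t"
           else ","
  # parse problems surface through check_parse(); readr's own chatter is
  # redundant with the structured errors raised there
  suppressWarnings(
    readr::read_delim(path, delim = delim, col_types = col_types,
                      show_col_types = FALSE, progress = FALSE))
}

check_parse <- function(df, what) {
  pb <- readr::problems(df)
  if (nrow(pb)) {
    # problems() counts the header line; report the data row
    abort(sprintf("%s: parse failure at row %d, column %s (%s).",
                  what, pb$row[1] - 1L, pb$col[1], pb$expected[1]))
  }
  df
}

#' Read a transition-level SRM measurement report
#'
#' Validates schema and types of a CSV/TSV report of integrated peak
#' areas (one row per peptide and sample). Duplicate peptide-sample rows
#' are rejected; non-numeric area fields raise an error with the row
#' number.
#'
#' @param path File path (`.csv` or `.tsv`).
#' @return Typed tibble with columns `peptide_id`, `protein_id`,
#'   `sample_id`, `light_area`, `heavy_area`, `apex_intensity`,
#'   `background_noise`, `heavy_spike_amol_per_ug`.
#' @export
read_transition_report <- function(path) {
  if (!file.exists(path)) abort(paste("File not found:", path))
  df <- read_delim_auto(path, readr::cols(
    peptide_id = readr::col_character(),
    protein_id = readr::col_character(),
    sample_id = readr::col_character(),
    light_area = readr::col_double(),
    heavy_area = readr::col_double(),
    apex_intensity = readr::col_double(),
    background_noise = readr::col_double(),
    heavy_spike_amol_per_ug = readr::col_double()))
  check_columns(df, c("peptide_id", "protein_id", "sample_id",
                      "light_area", "heavy_area", "apex_intensity",
                      "background_noise", "heavy_spike_amol_per_ug"),
                "transition report")
  check_parse(df, "transition report")
  dup <- df |>
    dplyr::count(.data$peptide_id, .data$sample_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(paste("Duplicate peptide x sample rows:",
                paste(paste(dup$peptide_id, dup$sample_id, sep = "/"),
                      collapse = ", ")))
  }
  df
}

#' Read a calibration-series table
#'
#' As [read_transition_report()] but with the calibration-specific columns
#' `spike_level_amol_per_ug` and `replicate`; duplicates are judged on
#' (peptide, spike level, replicate). The returned tibble carries the
#' computed heavy-over-light ratio and the `spike_conc` column expected by
#' [fit_response_curves()].
#'
#' @inheritParams read_transition_report
#' @return Typed tibble of calibration points.
#' @export
read_calibration_table <- function(path) {
  if (!file.exists(path)) abort(paste("File not found:", path))
  df <- read_delim_auto(path, readr::cols(
    peptide_id = readr::col_character(),
    protein_id = readr::col_character(),
    spike_level_amol_per_ug = readr::col_double(),
    replicate = readr::col_integer(),
    light_area = readr::col_double(),
    heavy_area = readr::col_double(),
    apex_intensity = readr::col_double(),
    background_noise = readr::col_double()))
  check_columns(df, c("peptide_id", "spike_level_amol_per_ug", "replicate",
                      "light_area", "heavy_area", "apex_intensity",
                      "background_noise"), "calibration table")
  check_parse(df, "calibration table")
  dup <- df |>
    dplyr::count(.data$peptide_id, .data$spike_level_amol_per_ug,
                 .data$replicate) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) abort("Duplicate peptide x level x replicate rows.")
  df |>
    dplyr::mutate(spike_conc = .data$spike_level_amol_per_ug,
                  hl_ratio = .data$heavy_area / .data$light_area)
}

cohort_levels <- list(
  outcome = c("nonevent", "bcr", "dm"),
  race = c("AA", "CA_other"),
  psa_dx = c("<10", "10-20", ">20"),
  clinical_t = c("T1-T2a", "T2b-T2c", "T3a-T4"),
  biopsy_grade = c("<=6", "7", "8-10"),
  nccn = c("low", "intermediate", "high"),
  path_t = c("pT2", "pT3-4"),
  margin = c("neg", "pos"))

#' Read and validate a cohort table
#'
#' Checks categorical columns against their allowed levels (unknown values
#' are an error) and flags nonevent patients with under 120 months of
#' follow-up, which contradicts the nonevent definition of at least ten
#' event-free years.
#'
#' @inheritParams read_transition_report
#' @return Typed cohort tibble.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) abort(paste("File not found:", path))
  df <- read_delim_auto(path, readr::cols(
    .default = readr::col_double(),
    patient_id = readr::col_character(),
    race = readr::col_character(),
    psa_dx = readr::col_character(),
    clinical_t = readr::col_character(),
    biopsy_grade = readr::col_character(),
    nccn = readr::col_character(),
    path_t = readr::col_character(),
    margin = readr::col_character(),
    outcome = readr::col_character()))
  check_columns(df, c("patient_id", "outcome", "followup"), "cohort table")
  check_parse(df, "cohort table")
  for (col in intersect(names(cohort_levels), names(df))) {
    bad <- setdiff(unique(df[[col]][!is.na(df[[col]])]),
                   cohort_levels[[col]])
    if (length(bad)) {
      abort(sprintf("Unknown %s level(s): %s", col,
                    paste(bad, collapse = ", ")))
    }
  }
  short <- df$outcome == "nonevent" & df$followup < 120
  if (any(short, na.rm = TRUE)) {
    warn(sprintf(
      "%d nonevent patient(s) have under 120 months of follow-up.",
      sum(short, na.rm = TRUE)))
  }
  df
}

#' Write pipeline tables as TSV
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the analysis constants: per-endpoint constraint sets
#' (metastasis: classifier NPV 0.90 / specificity 0.35, single markers
#' 0.80 / 0.40; recurrence single markers 0.70 / 0.30), the AUC retention
#' floor (0.60), the marker-count Bonferroni family (16 at alpha 0.05),
#' bootstrap size, split fraction, selection rules and the seed.
#'
#' @param markers Marker column names (default the 16 panel candidates).
#' @param transform `"log10z"` to analyze markers as z-scores of log10
#'   concentrations (the scale on which cut-points are reported), or
#'   `"none"` if the marker columns are already on the analysis scale.
#' @param gg_high Grade groups considered "high" for the grade endpoint
#'   (default `3:5`; the alternative convention is `4:5`).
#' @param B Bootstrap replicates (default 1000).
#' @param alpha,m Family-wise error rate and family size for the
#'   Bonferroni threshold.
#' @param auc_retain Minimum AUC for a marker to enter cut-point and panel
#'   analyses (default 0.60).
#' @param train_fraction,p_max,auc_min,min_npv,min_spec Classifier
#'   training constants (see [train_classifier()]).
#' @param cut_npv_dm,cut_spec_dm,cut_npv_bcr,cut_spec_bcr Single-marker
#'   constraint floors per endpoint.
#' @param seed Integer seed driving every random draw in the pipeline.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(markers = default_marker_effects()$marker,
                            transform = c("log10z", "none"),
                            gg_high = 3:5,
                            B = 1000, alpha = 0.05, m = 16,
                            auc_retain = 0.60,
                            train_fraction = 0.7,
                            p_max = 0.05, auc_min = 0.65,
                            min_npv = 0.90, min_spec = 0.35,
                            cut_npv_dm = 0.80, cut_spec_dm = 0.40,
                            cut_npv_bcr = 0.70, cut_spec_bcr = 0.30,
                            seed = 1L) {
  transform <- match.arg(transform)
  stopifnot(B >= 1, alpha > 0, alpha < 1)
  for (v in c(min_npv, min_spec, cut_npv_dm, cut_spec_dm, cut_npv_bcr,
              cut_spec_bcr)) {
    if (v < 0 || v > 1) abort("Constraints must lie in [0, 1].")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Standardized log10 transform of marker concentrations
#'
#' Converts raw concentrations (amol/ug) to z-scores of log10 values, the
#' scale on which marker cut-points are reported. Zeros (e.g. clamped
#' below-detection values) are offset by half the smallest positive value
#' of the marker before taking logs.
#'
#' @param data Tibble with marker columns.
#' @param markers Marker column names.
#' @return `data` with the marker columns replaced by standardized log10
#'   values.
#' @export
transform_log10z <- function(data, markers) {
  check_columns(data, markers, "marker data")
  dplyr::mutate(data, dplyr::across(
    dplyr::all_of(markers),
    function(x) {
      if (any(x < 0, na.rm = TRUE)) abort("Concentrations must be >= 0.")
      if (any(x == 0, na.rm = TRUE)) {
        x <- x + min(x[x > 0], na.rm = TRUE) / 2
      }
      lx <- log10(x)
      as.numeric(scale(lx))
    }))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole route from inputs to report tables: optional
#' quantification of a transition report against a calibration series,
#' marker transformation, the cohort summary, per-marker AUC tables for
#' the three endpoints (metastasis vs nonevent, recurrence vs nonevent,
#' high vs low grade group), constrained cut-points and survival analyses
#' for retained markers, the principal-component panel screen, and
#' training/testing of the panel classifier with its constrained
#' threshold, likelihood-ratio added-value tests and Cox models.
#'
#' @param cohort Cohort tibble (see [read_cohort_table()]); marker columns
#'   are either present already or joined from the quantified report.
#' @param config A [pipeline_config()].
#' @param report Optional transition report (raw entry mode); requires
#'   `calibration`.
#' @param calibration Optional calibration table (see
#'   [read_calibration_table()]).
#' @return List of class `pipeline_result` with elements
#'   `cohort_summary`, `marker_auc` (per endpoint), `cutpoints`,
#'   `survival` (log-rank tables), `pca`, `selection`, `model`,
#'   `test_metrics`, `test_auc`, `lrt`, `cox`, `curves` (when
#'   quantifying), and `log` (character vector of stage notes). Given the
#'   same seed the result is reproducible.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         report = NULL, calibration = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  curves <- NULL

  if (!is.null(report)) {
    if (is.null(calibration)) {
      abort("Stage quantify: raw mode needs a `calibration` table.")
    }
    curves <- fit_response_curves(calibration)
    conc <- quantify_samples(report, curves, format = "long")
    wide <- conc |>
      dplyr::select("protein_id", "sample_id", "c_endogenous") |>
      tidyr::pivot_wider(names_from = "protein_id",
                         values_from = "c_endogenous")
    cohort <- dplyr::inner_join(cohort, wide,
                                by = c(patient_id = "sample_id"))
    note("quantify: %d proteins x %d samples", dplyr::n_distinct(conc$protein_id),
         dplyr::n_distinct(conc$sample_id))
  }
  markers <- intersect(config$markers, names(cohort))
  if (length(markers) == 0L) abort("Stage markers: no marker columns found.")
  if (config$transform == "log10z") {
    cohort <- transform_log10z(cohort, markers)
    note("transform: log10 z-scores for %d markers", length(markers))
  }

  cohort_summary <- summarize_cohort(
    cohort, group = "outcome",
    vars = intersect(c("age_at_dx", "race", "psa_dx", "clinical_t",
                       "biopsy_grade", "nccn", "path_t", "grade_group",
                       "margin", "followup"), names(cohort)))

  endpoints <- list(
    dm_vs_nonevent = dplyr::filter(cohort,
                                   .data$outcome %in% c("dm", "nonevent")) |>
      dplyr::mutate(.y = as.integer(.data$outcome == "dm")),
    bcr_vs_nonevent = dplyr::filter(cohort,
                                    .data$outcome %in% c("bcr",
                                                         "nonevent")) |>
      dplyr::mutate(.y = as.integer(.data$outcome == "bcr")))
  if ("grade_group" %in% names(cohort)) {
    gg <- dplyr::filter(cohort, !is.na(.data$grade_group)) |>
      dplyr::mutate(.y = as.integer(.data$grade_group %in% config$gg_high))
    endpoints$high_gg_vs_low_gg <- gg
  }
  auc_tables <- purrr::imap(endpoints, function(d, nm) {
    evaluate_markers(d, markers, ".y", B = config$B, seed = config$seed)
  })
  bonf <- bonferroni_threshold(config$alpha, config$m)

  constraint <- list(dm_vs_nonevent = c(config$cut_npv_dm,
                                        config$cut_spec_dm),
                     bcr_vs_nonevent = c(config$cut_npv_bcr,
                                         config$cut_spec_bcr))
  cutpoints <- purrr::imap(auc_tables[names(constraint)], function(tb, nm) {
    retained <- tb$marker[pmax(tb$auc, 1 - tb$auc) >= config$auc_retain]
    note("%s: %d marker(s) at AUC >= %.2f", nm, length(retained),
         config$auc_retain)
    if (length(retained) == 0L) return(NULL)
    find_cutpoints(endpoints[[nm]], retained, ".y",
                   min_npv = constraint[[nm]][1],
                   min_spec = constraint[[nm]][2],
                   B = config$B, seed = config$seed)
  })

  survival_tables <- purrr::imap(cutpoints, function(cp, nm) {
    if (is.null(cp)) return(NULL)
    d <- endpoints[[nm]]
    if (nm == "dm_vs_nonevent") {
      tm <- ifelse(d$outcome == "dm", d$time_to_dm, d$followup)
      ev <- as.integer(d$outcome == "dm")
    } else {
      tm <- ifelse(d$outcome == "bcr", d$time_to_bcr, d$followup)
      ev <- as.integer(d$outcome == "bcr")
    }
    purrr::pmap_dfr(cp[c("marker", "cutpoint", "direction", "feasible")],
                    function(marker, cutpoint, direction, feasible) {
      if (!feasible) {
        return(tibble::tibble(marker = marker, chi_squared = NA_real_,
                              df = NA_real_, p_value = NA_real_,
                              n = NA_integer_))
      }
      high <- if (direction == "high_risk") d[[marker]] >= cutpoint else
        d[[marker]] <= cutpoint
      lr <- logrank_test(tm, ev, ifelse(high, "high", "low"))
      dplyr::bind_cols(tibble::tibble(marker = marker), lr)
    })
  })

  sig <- auc_tables$dm_vs_nonevent
  panel_candidates <- sig$marker[pmax(sig$auc, 1 - sig$auc) >=
                                   config$auc_retain]
  pca <- if (length(panel_candidates) >= 2L) {
    pca_panel_screen(cohort, panel_candidates)
  } else NULL

  dmne <- endpoints$dm_vs_nonevent
  split <- split_cohort(dmne, train_fraction = config$train_fraction,
                        outcome = ".y", seed = config$seed)
  model <- train_classifier(split$train, markers, ".y",
                            p_max = config$p_max, auc_min = config$auc_min,
                            min_npv = config$min_npv,
                            min_spec = config$min_spec,
                            B = config$B, seed = config$seed)
  note("classifier: %d marker(s) selected; threshold %.3f (feasible: %s)",
       length(model$markers), model$threshold %||% NA,
       model$threshold_feasible)
  test_scored <- score_patients(model, split$test)
  test_metrics <- evaluate_at_threshold(test_scored$score, test_scored$.y,
                                        model$threshold)
  test_auc <- marker_auc(test_scored$score, test_scored$.y, B = config$B,
                         seed = config$seed)

  lrt <- tryCatch({
    soc_vars <- intersect(c("age_at_dx", "race", "nccn"),
                          names(test_scored))
    dd <- test_scored[complete.cases(test_scored[c(".y", soc_vars,
                                                   "score")]), ]
    base <- glm(as.formula(paste(".y ~", paste(soc_vars, collapse = "+"))),
                data = dd, family = binomial())
    full <- glm(as.formula(paste(".y ~", paste(c(soc_vars, "score"),
                                               collapse = "+"))),
                data = dd, family = binomial())
    compare_models_lrt(base, full)
  }, error = function(e) {
    note("lrt skipped: %s", conditionMessage(e)); NULL
  })

  cox <- tryCatch({
    td <- test_scored |>
      dplyr::mutate(
        dm_time = ifelse(.data$outcome == "dm", .data$time_to_dm,
                         .data$followup),
        dm_event = as.integer(.data$outcome == "dm"))
    purrr::map(
      setNames(c("biopsy", "pathology"), c("biopsy", "pathology")),
      function(s) {
        list(
          dichotomous = cox_classifier(td, "dm_time", "dm_event", soc = s,
                                       classifier = "dichotomous",
                                       threshold = model$threshold),
          continuous = cox_classifier(td, "dm_time", "dm_event", soc = s,
                                      classifier = "continuous"))
      })
  }, error = function(e) {
    note("cox skipped: %s", conditionMessage(e)); NULL
  })

  structure(list(
    cohort_summary = cohort_summary,
    marker_auc = auc_tables,
    bonferroni = bonf,
    cutpoints = cutpoints,
    survival = survival_tables,
    pca = pca,
    split = split,
    model = model,
    test_metrics = test_metrics,
    test_auc = test_auc,
    lrt = lrt,
    cox = cox,
    curves = curves,
    log = log), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("srmpanel pipeline result\n")
  cat(" markers evaluated:", nrow(x$marker_auc[[1]]), "\n")
  cat(" classifier markers:", paste(x$model$markers, collapse = ", "),
      "\n")
  cat(" threshold:", round(x$model$threshold, 2), "(0-100 score)\n")
  cat(" test metrics: sens", round(x$test_metrics$sensitivity, 3),
      "spec", round(x$test_metrics$specificity, 3),
      "npv", round(x$test_metrics$npv, 3), "\n")
  invisible(x)
}
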