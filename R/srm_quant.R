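#' Signal-to-noise ratio of an SRM peak
#'
#' Ratio of the chromatographic peak apex intensity to the highest background
#' noise in a retention-time window around the peak (the window width is an
#' acquisition-side choice; integrated values arrive here as plain numbers).
#'
#' @param apex_intensity Peak apex intensity in counts (non-negative).
#' @param background_noise Highest background intensity near the peak, counts
#'   (non-negative). A zero background with a positive apex yields `Inf`,
#'   the conventional "no measurable background" sentinel; `0 / 0` yields
#'   `NA`.
#' @return Numeric vector of S/N ratios, recycled to the common length.
#' @examples
#' compute_snr(300, 100)
#' compute_snr(c(500, 0), c(0, 0))
#' @export
compute_snr <- function(apex_intensity, background_noise) {
  if (any(apex_intensity < 0, na.rm = TRUE)) {
    abort("`apex_intensity` must be non-negative.")
  }
  if (any(background_noise < 0, na.rm = TRUE)) {
    abort("`background_noise` must be non-negative.")
  }
  snr <- apex_intensity / background_noise
  snr[background_noise == 0 & apex_intensity > 0] <- Inf
  snr[background_noise == 0 & apex_intensity == 0] <- NA_real_
  snr
}

#' Fit a linear calibration (response) curve for one peptide
#'
#' Ordinary least squares of the heavy-over-light peak-area ratio on the
#' spiked heavy-peptide concentration, `H/L = slope * conc + intercept`.
#' All replicate points enter the fit individually.
#'
#' @param points Data frame of calibration points with columns `spike_conc`
#'   (amol/ug) and `hl_ratio` (heavy-over-light peak-area ratio).
#' @return One-row tibble with `slope` (per amol/ug), `intercept`,
#'   `r_squared` and `n_points`.
#' @examples
#' pts <- tibble::tibble(spike_conc = c(0, 1, 2), hl_ratio = c(0, 1, 2))
#' fit_response_curve(pts)
#' @export
fit_response_curve <- function(points) {
  check_columns(points, c("spike_conc", "hl_ratio"), "calibration points")
  pts <- dplyr::filter(points, is.finite(.data$hl_ratio),
                       is.finite(.data$spike_conc))
  if (any(pts$hl_ratio < 0)) abort("`hl_ratio` must be non-negative.")
  if (dplyr::n_distinct(pts$spike_conc) < 2L) {
    abort("All calibration points share one spike level; the fit is singular.")
  }
  if (dplyr::n_distinct(pts$spike_conc) < 3L) {
    warn("Fewer than 3 distinct spike levels; the curve is poorly constrained.")
  }
  fit <- lm(hl_ratio ~ spike_conc, data = pts)
  tibble::tibble(
    slope = unname(coef(fit)[["spike_conc"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n_points = nrow(pts)
  )
}

#' Limits of detection and quantification from replicate calibration data
#'
#' The LOD is the lowest non-zero spike level whose replicate-median
#' signal-to-noise ratio reaches 3; the LOQ additionally requires S/N of at
#' least 10 and a replicate coefficient of variation of the H/L ratio below
#' 20%. Levels are judged independently; a level with fewer than two
#' replicates has no defined CV and cannot qualify as LOQ.
#'
#' @param points Data frame with columns `spike_conc`, `replicate`,
#'   `hl_ratio`, `apex_intensity`, `background_noise`.
#' @param snr_lod,snr_loq S/N thresholds (defaults 3 and 10).
#' @param cv_max Maximum replicate CV of the H/L ratio for the LOQ (0.20).
#' @return One-row tibble with `lod` and `loq` in amol/ug; `NA` marks a
#'   limit no level qualifies for (undetectable assays do occur, e.g. when
#'   heavy-transition interference swamps the signal).
#' @export
determine_lod_loq <- function(points, snr_lod = 3, snr_loq = 10,
                              cv_max = 0.20) {
  check_columns(points, c("spike_conc", "hl_ratio", "apex_intensity",
                          "background_noise"), "calibration points")
  if (nrow(points) == 0L) abort("No calibration levels supplied.")
  by_level <- points |>
    dplyr::filter(.data$spike_conc > 0) |>
    dplyr::group_by(.data$spike_conc) |>
    dplyr::summarise(
      snr_med = median(compute_snr(.data$apex_intensity,
                                   .data$background_noise), na.rm = TRUE),
      cv = if (dplyr::n() >= 2L) {
        sd(.data$hl_ratio) / mean(.data$hl_ratio)
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$spike_conc)
  lod_levels <- by_level$spike_conc[by_level$snr_med >= snr_lod]
  loq_levels <- by_level$spike_conc[by_level$snr_med >= snr_loq &
                                      !is.na(by_level$cv) &
                                      by_level$cv < cv_max]
  tibble::tibble(
    lod = if (length(lod_levels)) min(lod_levels) else NA_real_,
    loq = if (length(loq_levels)) min(loq_levels) else NA_real_
  )
}

#' Light-peptide concentration in the pooled calibration matrix
#'
#' The calibration series spikes heavy peptide into a pooled sample whose
#' endogenous (light) peptide content is unknown but constant. At a spike
#' level X the measured H/L ratio, corrected for the curve intercept,
#' estimates `X / c_light`; inverting and averaging over the designated
#' mid-curve levels gives the matrix light concentration used by
#' [endogenous_concentration()].
#'
#' @param curve One-row data frame with `slope` and `intercept` (from
#'   [fit_response_curve()]).
#' @param points Calibration points (`spike_conc`, `hl_ratio`).
#' @param levels Spike levels used for the estimate; default
#'   `c(300, 1500, 3000)` amol/ug. Levels absent from `points` are dropped
#'   with a warning.
#' @return Scalar estimate of the light concentration (amol/ug).
#' @export
estimate_matrix_light_conc <- function(curve, points,
                                       levels = c(300, 1500, 3000)) {
  check_columns(points, c("spike_conc", "hl_ratio"), "calibration points")
  present <- intersect(levels, unique(points$spike_conc))
  if (length(present) == 0L) {
    abort("None of the requested spike levels are present in `points`.")
  }
  if (length(present) < length(levels)) {
    warn(sprintf("Spike level(s) %s missing; using %d level(s).",
                 paste(setdiff(levels, present), collapse = ", "),
                 length(present)))
  }
  per_level <- points |>
    dplyr::filter(.data$spike_conc %in% present) |>
    dplyr::group_by(.data$spike_conc) |>
    dplyr::summarise(hl_mean = mean(.data$hl_ratio), .groups = "drop") |>
    dplyr::mutate(
      corrected = .data$hl_mean - curve$intercept,
      c_light = .data$spike_conc / .data$corrected
    )
  usable <- per_level$c_light[per_level$corrected > 0]
  if (length(usable) == 0L) {
    abort("All intercept-corrected ratios are non-positive; cannot estimate the matrix light concentration.")
  }
  mean(usable)
}

#' Fit response curves, limits and matrix concentrations for many peptides
#'
#' Per-peptide wrapper around [fit_response_curve()], [determine_lod_loq()]
#' and [estimate_matrix_light_conc()].
#'
#' @param calibration Calibration table with columns `peptide_id`,
#'   `spike_conc`, `replicate`, `hl_ratio`, `apex_intensity`,
#'   `background_noise`.
#' @param light_levels Spike levels for the matrix light-concentration
#'   estimate.
#' @inheritParams determine_lod_loq
#' @return Tibble of class `response_curves`, one row per peptide:
#'   `peptide_id`, `slope`, `intercept`, `r_squared`, `n_points`, `lod`,
#'   `loq`, `c_light_matrix`.
#' @export
fit_response_curves <- function(calibration, light_levels = c(300, 1500, 3000),
                                snr_lod = 3, snr_loq = 10, cv_max = 0.20) {
  check_columns(calibration,
                c("peptide_id", "spike_conc", "hl_ratio",
                  "apex_intensity", "background_noise"),
                "calibration table")
  curves <- calibration |>
    dplyr::group_by(.data$peptide_id) |>
    dplyr::group_modify(function(pts, key) {
      fit <- fit_response_curve(pts)
      lims <- determine_lod_loq(pts, snr_lod = snr_lod, snr_loq = snr_loq,
                                cv_max = cv_max)
      fit$c_light_matrix <- estimate_matrix_light_conc(fit, pts,
                                                       levels = light_levels)
      dplyr::bind_cols(fit, lims)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$peptide_id)
  bad <- curves$peptide_id[!is.na(curves$lod) & !is.na(curves$loq) &
                             curves$lod > curves$loq]
  if (length(bad)) {
    warn(paste("LOD exceeds LOQ for:", paste(bad, collapse = ", ")))
  }
  class(curves) <- c("response_curves", class(curves))
  curves
}

#' Back-calculate endogenous peptide concentrations
#'
#' Inverts the calibration model for study samples. With a constant heavy
#' spike `c_heavy` and measured light-over-heavy ratio `lh`, the endogenous
#' concentration is
#' `c_endo = ((lh * c_heavy / c_light_matrix) - intercept) / slope`,
#' the algebraic inverse of the forward model under the equal-response
#' assumption (heavy and light forms of a peptide ionise identically).
#'
#' @param measurements Tibble with `peptide_id`, `sample_id`, `lh_ratio`
#'   (light-over-heavy peak-area ratio) and `c_heavy_spiked` (amol/ug).
#' @param curves `response_curves` tibble with `c_light_matrix` present.
#' @return Tibble with `peptide_id`, `sample_id`, `c_endogenous` (amol/ug)
#'   and `qc_flag` in `ok`, `below_loq`, `below_lod`, `negative_clamped`,
#'   `missing`. Negative back-calculations are clamped to zero; below-limit
#'   values keep their numeric estimate and are only flagged, so callers
#'   choose their own censoring policy.
#' @export
endogenous_concentration <- function(measurements, curves) {
  check_columns(measurements,
                c("peptide_id", "sample_id", "lh_ratio", "c_heavy_spiked"),
                "measurement table")
  check_columns(curves,
                c("peptide_id", "slope", "intercept", "c_light_matrix"),
                "response curves")
  unknown <- setdiff(unique(measurements$peptide_id), curves$peptide_id)
  if (length(unknown)) {
    abort(paste("No response curve for peptide(s):",
                paste(unknown, collapse = ", ")))
  }
  if (any(is.na(measurements$c_heavy_spiked) |
            measurements$c_heavy_spiked <= 0)) {
    abort("`c_heavy_spiked` must be present and positive for every measurement.")
  }
  bad_curve <- curves$peptide_id[curves$slope <= 0 | curves$c_light_matrix <= 0]
  bad_curve <- intersect(bad_curve, measurements$peptide_id)
  if (length(bad_curve)) {
    abort(paste("Unusable curve (slope or matrix light concentration <= 0) for:",
                paste(bad_curve, collapse = ", ")))
  }
  cw <- dplyr::select(curves, "peptide_id", "slope", "intercept",
                      "c_light_matrix",
                      dplyr::any_of(c("lod", "loq")))
  if (!"lod" %in% names(cw)) cw$lod <- NA_real_
  if (!"loq" %in% names(cw)) cw$loq <- NA_real_
  out <- measurements |>
    dplyr::left_join(cw, by = "peptide_id") |>
    dplyr::mutate(
      raw = ((.data$lh_ratio * .data$c_heavy_spiked / .data$c_light_matrix) -
               .data$intercept) / .data$slope,
      c_endogenous = pmax(.data$raw, 0),
      qc_flag = dplyr::case_when(
        is.na(.data$lh_ratio) ~ "missing",
        .data$raw < 0 ~ "negative_clamped",
        !is.na(.data$lod) & .data$c_endogenous < .data$lod ~ "below_lod",
        !is.na(.data$loq) & .data$c_endogenous < .data$loq ~ "below_loq",
        TRUE ~ "ok"
      )
    ) |>
    dplyr::mutate(c_endogenous = dplyr::if_else(.data$qc_flag == "missing",
                                                NA_real_,
                                                .data$c_endogenous)) |>
    dplyr::select("peptide_id", "sample_id", "c_endogenous", "qc_flag")
  out
}

#' Quantify a transition report into a protein-by-sample matrix
#'
#' Computes light-over-heavy ratios from integrated peak areas, back-
#' calculates endogenous concentrations per peptide via
#' [endogenous_concentration()], and rolls peptides up to proteins. The
#' default roll-up designates one surrogate peptide per protein; when a
#' protein is measured by several peptides a `surrogates` map must name the
#' designated one (or `rollup = "mean"` averages peptide concentrations).
#'
#' @param report Transition table with columns `peptide_id`, `protein_id`,
#'   `sample_id`, `light_area`, `heavy_area`, `heavy_spike_amol_per_ug`.
#' @param curves `response_curves` tibble.
#' @param surrogates Optional named character vector, `protein_id` ->
#'   `peptide_id`, designating surrogate peptides.
#' @param rollup `"surrogate"` (default) or `"mean"`.
#' @param format `"wide"` (proteins x samples, default) or `"long"`.
#' @return Wide: tibble with `protein_id` and one column per sample, with
#'   the long per-measurement QC table in attribute `"qc"`. Long: tibble
#'   `protein_id`, `sample_id`, `c_endogenous`, `qc_flag`. Rows and columns
#'   are sorted, so output ordering is deterministic.
#' @export
quantify_samples <- function(report, curves, surrogates = NULL,
                             rollup = c("surrogate", "mean"),
                             format = c("wide", "long")) {
  rollup <- match.arg(rollup)
  format <- match.arg(format)
  check_columns(report,
                c("peptide_id", "protein_id", "sample_id", "light_area",
                  "heavy_area", "heavy_spike_amol_per_ug"),
                "transition report")
  if (nrow(report) == 0L) {
    empty <- tibble::tibble(protein_id = character())
    return(if (format == "wide") empty else
      tibble::tibble(protein_id = character(), sample_id = character(),
                     c_endogenous = double(), qc_flag = character()))
  }
  dup <- report |>
    dplyr::count(.data$peptide_id, .data$sample_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(paste0("Duplicate sample x peptide rows: ",
                 paste(paste(dup$peptide_id, dup$sample_id, sep = "/"),
                       collapse = ", ")))
  }
  meas <- report |>
    dplyr::mutate(lh_ratio = .data$light_area / .data$heavy_area,
                  c_heavy_spiked = .data$heavy_spike_amol_per_ug)
  conc <- endogenous_concentration(meas, curves) |>
    dplyr::left_join(dplyr::distinct(report, .data$peptide_id,
                                     .data$protein_id),
                     by = "peptide_id")
  if (rollup == "surrogate") {
    multi <- conc |>
      dplyr::distinct(.data$protein_id, .data$peptide_id) |>
      dplyr::count(.data$protein_id) |>
      dplyr::filter(.data$n > 1L)
    if (nrow(multi) && is.null(surrogates)) {
      abort(paste("Multiple peptides for protein(s)",
                  paste(multi$protein_id, collapse = ", "),
                  "- supply a `surrogates` map or use rollup = \"mean\"."))
    }
    if (!is.null(surrogates)) {
      keep <- conc$peptide_id == surrogates[conc$protein_id] |
        !(conc$protein_id %in% names(surrogates))
      conc <- conc[keep, , drop = FALSE]
    }
    long <- conc |>
      dplyr::select("protein_id", "sample_id", "c_endogenous", "qc_flag")
  } else {
    long <- conc |>
      dplyr::group_by(.data$protein_id, .data$sample_id) |>
      dplyr::summarise(
        c_endogenous = mean(.data$c_endogenous, na.rm = TRUE),
        qc_flag = if (all(.data$qc_flag == "ok")) "ok" else
          paste(sort(unique(.data$qc_flag[.data$qc_flag != "ok"])),
                collapse = ";"),
        .groups = "drop"
      )
  }
  long <- dplyr::arrange(long, .data$protein_id, .data$sample_id)
  if (format == "long") return(long)
  wide <- long |>
    dplyr::select(-"qc_flag") |>
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = "c_endogenous") |>
    dplyr::arrange(.data$protein_id)
  attr(wide, "qc") <- long
  wide
}

# Shared column-presence check with a readable error.
check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) abort(paste0("`", what, "` must be a data frame."))
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
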