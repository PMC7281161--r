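test_that("signal-to-noise ratio handles direct, degenerate and planted cases", {
  expect_equal(compute_snr(300, 100), 3.0)
  expect_identical(compute_snr(500, 0), Inf)
  expect_true(is.na(compute_snr(0, 0)))
  # planted trace: max background 42, apex 420
  trace_bg <- c(10, 42, 7, 30)
  expect_equal(compute_snr(420, max(trace_bg)), 10.0)
  expect_error(compute_snr(-1, 10), "non-negative")
  expect_error(compute_snr(10, -1), "non-negative")
})

test_that("response-curve fit recovers noiseless lines exactly", {
  cal <- make_calibration(slope = 0.002, intercept = 0.01)
  fit <- fit_response_curve(cal)
  expect_equal(fit$slope, 0.002, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.01, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  fit2 <- fit_response_curve(
    tibble::tibble(spike_conc = c(0, 1, 2), hl_ratio = c(0, 1, 2)))
  expect_equal(fit2$slope, 1)
  expect_equal(fit2$intercept, 0, tolerance = 1e-12)
})

test_that("response-curve fit equals the closed-form OLS solution", {
  for (s in 1:25) {
    n <- sample(3:30, 1)
    pts <- withr::with_seed(s, tibble::tibble(
      spike_conc = runif(n, 0, 1000),
      hl_ratio = abs(rnorm(n, 1, 0.5))))
    fit <- fit_response_curve(pts)
    oracle <- oracle_ols(pts$spike_conc, pts$hl_ratio)
    expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(oracle["intercept"]),
                 tolerance = 1e-10)
  }
})

test_that("degenerate calibration designs are rejected", {
  pts <- tibble::tibble(spike_conc = rep(10, 4), hl_ratio = 1:4)
  expect_error(fit_response_curve(pts), "singular")
  expect_error(determine_lod_loq(tibble::tibble(
    spike_conc = numeric(0), hl_ratio = numeric(0),
    apex_intensity = numeric(0), background_noise = numeric(0))),
    "No calibration")
})

snr_table <- function(snr_by_level, cv_by_level) {
  # three replicates per level; hl values tuned to the requested CV
  purrr::imap_dfr(snr_by_level, function(snr, lvl) {
    lvl <- as.numeric(lvl)
    cv <- cv_by_level[[as.character(lvl)]]
    tibble::tibble(
      spike_conc = lvl, replicate = 1:3,
      hl_ratio = 1 + cv * c(-1, 0, 1),   # sd = cv, mean = 1
      apex_intensity = snr * 100, background_noise = 100)
  })
}

test_that("LOD/LOQ rules: S/N floors plus the CV gate on the LOQ", {
  cv5 <- list(`0.6` = 0.05, `3` = 0.05, `12` = 0.05, `60` = 0.05)
  tab <- snr_table(list(`0.6` = 1, `3` = 4, `12` = 11, `60` = 40), cv5)
  lim <- determine_lod_loq(tab)
  expect_equal(lim$lod, 3)
  expect_equal(lim$loq, 12)

  # CV 25% at the first S/N >= 10 level pushes the LOQ up a level
  cvs <- list(`0.6` = 0.05, `3` = 0.05, `12` = 0.25, `60` = 0.08)
  tab2 <- snr_table(list(`0.6` = 1, `3` = 4, `12` = 11, `60` = 40), cvs)
  lim2 <- determine_lod_loq(tab2)
  expect_equal(lim2$lod, 3)
  expect_equal(lim2$loq, 60)

  # nothing reaches S/N 3: undetermined assay
  tab3 <- snr_table(list(`3` = 0.5, `12` = 1, `60` = 2),
                    list(`3` = 0.05, `12` = 0.05, `60` = 0.05))
  lim3 <- determine_lod_loq(tab3)
  expect_true(is.na(lim3$lod))
  expect_true(is.na(lim3$loq))
})

test_that("LOD never exceeds LOQ when both are defined", {
  for (s in 1:20) {
    cal <- make_calibration(slope = 1 / 500, intercept = 0.02,
                            lod = sample(c(3, 12, 60), 1), cv = 0.05,
                            seed = s)
    lim <- determine_lod_loq(cal)
    if (!is.na(lim$lod) && !is.na(lim$loq)) {
      expect_lte(lim$lod, lim$loq)
    }
  }
})

test_that("matrix light concentration: ideal response inverts to the truth", {
  # light 500 => H/L = spike/500 at the three mid-curve levels
  pts <- tibble::tibble(spike_conc = c(300, 1500, 3000),
                        hl_ratio = c(0.6, 3.0, 6.0))
  curve <- tibble::tibble(slope = 1 / 500, intercept = 0)
  expect_equal(estimate_matrix_light_conc(curve, pts), 500)

  # per-level estimates {400, 500, 600} average to 500
  pts2 <- tibble::tibble(spike_conc = c(300, 1500, 3000),
                         hl_ratio = c(300 / 400, 1500 / 500, 3000 / 600))
  expect_equal(estimate_matrix_light_conc(curve, pts2), 500)
})

test_that("matrix light concentration recovers a noisy forward simulation", {
  true_light <- 250
  cv <- 0.05
  ests <- vapply(1:30, function(s) {
    pts <- withr::with_seed(s, tibble::tibble(
      spike_conc = rep(c(300, 1500, 3000), each = 3),
      hl_ratio = (rep(c(300, 1500, 3000), each = 3) / true_light) *
        exp(rnorm(9, 0, sqrt(log(1 + cv^2))))))
    estimate_matrix_light_conc(tibble::tibble(slope = 1 / true_light,
                                              intercept = 0), pts)
  }, numeric(1))
  expect_lt(median(abs(ests - true_light)),
            2 * cv / sqrt(3) * true_light)
})

test_that("matrix light estimate drops non-positive corrected ratios", {
  curve <- tibble::tibble(slope = 1 / 500, intercept = 0.5)
  pts <- tibble::tibble(spike_conc = c(300, 1500, 3000),
                        hl_ratio = c(0.4, 3.5, 6.5))   # 300 level excluded
  est <- estimate_matrix_light_conc(curve, pts)
  expect_equal(est, mean(c(1500 / 3, 3000 / 6)))
  pts_bad <- tibble::tibble(spike_conc = c(300, 1500, 3000),
                            hl_ratio = c(0.1, 0.2, 0.3))
  expect_error(estimate_matrix_light_conc(curve, pts_bad), "non-positive")
})

ideal_curve <- function(c_light = 500, intercept = 0, lod = NA_real_,
                        loq = NA_real_, peptide = "PEP_A") {
  tibble::tibble(peptide_id = peptide, slope = 1 / c_light,
                 intercept = intercept, c_light_matrix = c_light,
                 lod = lod, loq = loq)
}

test_that("endogenous concentration inverts the calibration model", {
  m <- tibble::tibble(peptide_id = "PEP_A", sample_id = "S1",
                      lh_ratio = 0.5, c_heavy_spiked = 300)
  res <- endogenous_concentration(m, ideal_curve())
  expect_equal(res$c_endogenous, 150)
  expect_equal(res$qc_flag, "ok")
  # the ideal-truth check: L/H x spike
  expect_equal(res$c_endogenous, 0.5 * 300)

  zero <- endogenous_concentration(
    tibble::tibble(peptide_id = "PEP_A", sample_id = "S1",
                   lh_ratio = 0, c_heavy_spiked = 300),
    ideal_curve(lod = 12, loq = 60))
  expect_equal(zero$c_endogenous, 0)
  expect_equal(zero$qc_flag, "below_lod")
})

test_that("noiseless forward model round-trips through Eq-style inversion", {
  slope <- 1 / 400; intercept <- 0.05; c_light <- 400
  c_true <- 800; spike <- 300
  lh <- (slope * c_true + intercept) * c_light / spike
  res <- endogenous_concentration(
    tibble::tibble(peptide_id = "PEP_A", sample_id = "S1",
                   lh_ratio = lh, c_heavy_spiked = spike),
    ideal_curve(c_light = c_light, intercept = intercept))
  expect_equal(res$c_endogenous, 800, tolerance = 1e-9)
})

test_that("round-trip identity holds for randomized curve parameters", {
  for (s in 1:50) {
    p <- withr::with_seed(s, list(
      slope = runif(1, 1e-4, 1e-2), intercept = runif(1, 0, 0.2),
      c_light = runif(1, 50, 5000), c_true = runif(1, 0, 2000),
      spike = runif(1, 100, 1000)))
    lh <- (p$slope * p$c_true + p$intercept) * p$c_light / p$spike
    curve <- tibble::tibble(peptide_id = "X", slope = p$slope,
                            intercept = p$intercept,
                            c_light_matrix = p$c_light,
                            lod = NA_real_, loq = NA_real_)
    res <- endogenous_concentration(
      tibble::tibble(peptide_id = "X", sample_id = "S",
                     lh_ratio = lh, c_heavy_spiked = p$spike), curve)
    expect_equal(res$c_endogenous, p$c_true, tolerance = 1e-9)
  }
})

test_that("endogenous concentration is strictly increasing in the ratio", {
  lh <- seq(0.1, 2, by = 0.1)
  res <- endogenous_concentration(
    tibble::tibble(peptide_id = "PEP_A",
                   sample_id = sprintf("S%02d", seq_along(lh)),
                   lh_ratio = lh, c_heavy_spiked = 300),
    ideal_curve(intercept = 0.05))
  expect_true(all(diff(res$c_endogenous[order(res$sample_id)]) > 0))
})

test_that("concentration contract errors: spikes, curves, clamping", {
  expect_error(endogenous_concentration(
    tibble::tibble(peptide_id = "PEP_A", sample_id = "S1",
                   lh_ratio = 0.5, c_heavy_spiked = NA_real_),
    ideal_curve()), "positive")
  expect_error(endogenous_concentration(
    tibble::tibble(peptide_id = "PEP_B", sample_id = "S1",
                   lh_ratio = 0.5, c_heavy_spiked = 300),
    ideal_curve()), "PEP_B")
  # negative back-calculation clamps and flags
  res <- endogenous_concentration(
    tibble::tibble(peptide_id = "PEP_A", sample_id = "S1",
                   lh_ratio = 0.01, c_heavy_spiked = 300),
    ideal_curve(intercept = 0.5))
  expect_equal(res$c_endogenous, 0)
  expect_equal(res$qc_flag, "negative_clamped")
})

test_that("quantify_samples round-trips a noiseless two-peptide report", {
  curves <- dplyr::bind_rows(ideal_curve(c_light = 500, peptide = "PEP_A"),
                             ideal_curve(c_light = 250, peptide = "PEP_B"))
  truth <- tidyr::expand_grid(
    peptide_id = c("PEP_A", "PEP_B"),
    sample_id = c("S1", "S2", "S3")) |>
    dplyr::mutate(c_true = c(100, 200, 300, 50, 75, 125))
  report <- truth |>
    dplyr::left_join(curves, by = "peptide_id") |>
    dplyr::mutate(
      protein_id = sub("PEP_", "", peptide_id),
      heavy_spike_amol_per_ug = 300,
      lh = (slope * c_true + intercept) * c_light_matrix / 300,
      heavy_area = 1e5, light_area = lh * 1e5) |>
    dplyr::select(peptide_id, protein_id, sample_id, light_area,
                  heavy_area, heavy_spike_amol_per_ug) |>
    dplyr::mutate(apex_intensity = 1000, background_noise = 10)
  wide <- quantify_samples(report, curves)
  expect_equal(wide$protein_id, c("A", "B"))
  expect_equal(unlist(wide[wide$protein_id == "A", c("S1", "S2", "S3")],
                      use.names = FALSE), c(100, 200, 300),
               tolerance = 1e-9)
  expect_equal(unlist(wide[wide$protein_id == "B", c("S1", "S2", "S3")],
                      use.names = FALSE), c(50, 75, 125),
               tolerance = 1e-9)

  long <- quantify_samples(report, curves, format = "long")
  expect_equal(nrow(long), 6L)
  expect_true(all(long$qc_flag == "ok"))
})

test_that("quantify_samples contract: empty input, unknown peptides, duplicates", {
  curves <- ideal_curve()
  empty <- quantify_samples(
    tibble::tibble(peptide_id = character(), protein_id = character(),
                   sample_id = character(), light_area = double(),
                   heavy_area = double(), apex_intensity = double(),
                   background_noise = double(),
                   heavy_spike_amol_per_ug = double()), curves)
  expect_equal(nrow(empty), 0L)

  row <- tibble::tibble(peptide_id = "PEP_Z", protein_id = "Z",
                        sample_id = "S1", light_area = 1, heavy_area = 1,
                        apex_intensity = 1, background_noise = 1,
                        heavy_spike_amol_per_ug = 300)
  expect_error(quantify_samples(row, curves), "PEP_Z")
  dup <- dplyr::bind_rows(row, row) |>
    dplyr::mutate(peptide_id = "PEP_A", protein_id = "A")
  expect_error(quantify_samples(dup, curves), "Duplicate")
})
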