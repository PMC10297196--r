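test_that("closed-form lognormal moment matching reproduces the analytic solution", {
  par <- lognormal_moments(9370, 11690)
  # sigma^2 = log(1 + (sd/mean)^2), mu = log(mean) - sigma^2/2
  expect_equal(unname(par[["sdlog"]]), 0.9691, tolerance = 1e-3)
  expect_equal(unname(par[["meanlog"]]), 8.6756, tolerance = 1e-4)
  # round trip: the matched lognormal has the requested untruncated moments
  m <- exp(par[["meanlog"]] + par[["sdlog"]]^2 / 2)
  v <- (exp(par[["sdlog"]]^2) - 1) * m^2
  expect_equal(m, 9370, tolerance = 1e-10)
  expect_equal(sqrt(v), 11690, tolerance = 1e-10)
})

test_that("volume sampling respects bounds, determinism and the empty case", {
  cfg <- cohort_config(seed = 11)
  expect_identical(sample_volumes(cfg, 0), numeric(0))
  v1 <- sample_volumes(cfg, 500)
  v2 <- sample_volumes(cfg, 500)
  expect_identical(v1, v2)
  expect_true(all(v1 >= cfg$volume_min_mm3 & v1 <= cfg$volume_max_mm3))
})

test_that("sampled volumes match the truncated-distribution mean (numeric-integration oracle)", {
  cfg <- cohort_config(seed = 5)
  v <- sample_volumes(cfg, 1e5)
  par <- camvol:::calibrate_truncated_lognormal(
    cfg$volume_mean_mm3, cfg$volume_sd_mm3, cfg$volume_min_mm3, cfg$volume_max_mm3)
  mass <- integrate(function(x) dlnorm(x, par[["meanlog"]], par[["sdlog"]]),
                    cfg$volume_min_mm3, cfg$volume_max_mm3, rel.tol = 1e-10)$value
  mu_trunc <- integrate(function(x) x * dlnorm(x, par[["meanlog"]], par[["sdlog"]]),
                        cfg$volume_min_mm3, cfg$volume_max_mm3, rel.tol = 1e-10)$value / mass
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - mu_trunc), 3 * se)
  # the calibrated truncated distribution is centred on the requested mean
  expect_equal(mu_trunc, cfg$volume_mean_mm3, tolerance = 1e-3)
})

test_that("the default cohort reproduces the reference structure", {
  coh <- generate_cohort(cohort_config(seed = 42))
  expect_equal(nrow(coh$images), 147)
  expect_equal(nrow(coh$nodules), 208)
  expect_equal(unname(table(coh$images$n_nodules)[c("1", "2", "3")]),
               c(104, 25, 18), ignore_attr = TRUE)
  expect_equal(length(unique(coh$nodules$patient_id)), 72)
})

test_that("degenerate configurations yield empty cohorts", {
  cfg <- cohort_config(n_images_by_nodule_count = c("1" = 0L, "2" = 0L, "3" = 0L),
                       n_patients = 0L)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$nodules), 0)
  expect_equal(nrow(coh$images), 0)
})

test_that("a fixed seed reproduces the cohort exactly", {
  c1 <- generate_cohort(cohort_config(seed = 42))
  c2 <- generate_cohort(cohort_config(seed = 42))
  expect_identical(c1$nodules, c2$nodules)
  expect_identical(c1$images, c2$images)
})

test_that("truth rows satisfy the nodule invariants", {
  nod <- generate_cohort(cohort_config(seed = 3))$nodules
  expect_true(all(nod$true_volume_mm3 > 0))
  r <- (3 * nod$true_volume_mm3 / (4 * pi))^(1 / 3)
  expect_equal(nod$projected_radius_mm, r, tolerance = 1e-6)
  expect_true(all(nod$peak_probability > 0.2 & nod$peak_probability <= 1))
  expect_true(all(nod$true_volume_mm3 >= 110 & nod$true_volume_mm3 <= 70400))
  expect_equal(nod$area_mm2, pi * nod$apparent_radius_mm^2)
})

test_that("every follow-up image has a same-patient baseline at an earlier timepoint", {
  coh <- generate_cohort(cohort_config(seed = 8))
  img <- coh$images
  for (i in which(img$timepoint > 0)) {
    expect_true(any(img$patient_id == img$patient_id[i] &
                    img$timepoint == img$timepoint[i] - 1))
  }
  expect_true(all(tapply(img$timepoint, img$patient_id, length) >= 2))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(volume_min_mm3 = 10000, volume_mean_mm3 = 9370),
               "min < mean < max")
  expect_error(cohort_config(n_images_by_nodule_count = c("1" = -1L, "2" = 0L, "3" = 0L)),
               "non-negative")
  expect_error(generate_cohort(
    cohort_config(n_images_by_nodule_count = c("1" = 1L, "2" = 0L, "3" = 0L),
                  n_patients = 1L)),
    "serial pairs")
})

test_that("rendered maps honour the blob geometry and value range", {
  cfg <- cohort_config(grid_size = c(64, 64), pixel_spacing_mm = 1, seed = 1)
  empty <- render_probability_map(
    generate_cohort(cohort_config(n_images_by_nodule_count = c("1"=0L,"2"=0L,"3"=0L),
                                  n_patients = 0L))$nodules, cfg)
  expect_true(all(empty$values == 0))

  nod <- tibble::tibble(center_row = 32, center_col = 32,
                        peak_probability = 0.8, apparent_radius_mm = 10)
  m <- render_probability_map(nod, cfg)
  expect_gte(min(m$values), 0)
  expect_lte(max(m$values), 1)
  # pixel count above the 0.2 contour ~ analytic disc area pi * 10^2
  expect_lt(abs(sum(m$values > 0.2) - pi * 100) / (pi * 100), 0.05)

  bad <- tibble::tibble(center_row = 200, center_col = 32,
                        peak_probability = 0.8, apparent_radius_mm = 10)
  expect_error(render_probability_map(bad, cfg), "placement error")
})

test_that("extraction recovers the forward-modeled area within pixelization tolerance", {
  cfg <- cohort_config(grid_size = c(256, 256), pixel_spacing_mm = 1, seed = 2)
  # generic (non-integer) contour radii: radii with many lattice points
  # exactly on the 0.2 contour are degenerate for strict-threshold counting
  for (r_mm in c(5.3, 8.7, 14.2, 19.6)) {
    for (peak in c(0.35, 0.6, 0.95)) {
      nod <- tibble::tibble(center_row = 128, center_col = 128,
                            peak_probability = peak, apparent_radius_mm = r_mm)
      rois <- extract_rois(render_probability_map(nod, cfg))
      expect_equal(nrow(rois), 1)
      expect_lt(abs(rois$area_mm2 - pi * r_mm^2) / (pi * r_mm^2), 0.05)
      # blob-profile mean over the contour approaches the analytic value
      # (pixelization excludes part of the low-probability boundary ring)
      expect_equal(rois$prob_mean, (peak - 0.2) / log(peak / 0.2), tolerance = 0.1)
    }
  }
})

test_that("cohort correlations sit in the calibration bands", {
  # property over several seeds: Monte-Carlo mean of the three Spearman
  # correlations is close to the calibration targets
  rhos <- sapply(c(101, 202, 303, 404, 505), function(s) {
    n <- generate_cohort(cohort_config(seed = s))$nodules
    c(spearman_rho(n$area_mm2, n$true_volume_mm3),
      spearman_rho(n$area_mm2, n$prob_mean),
      spearman_rho(n$prob_mean, n$true_volume_mm3))
  })
  m <- rowMeans(rhos)
  expect_lt(abs(m[1] - 0.58), 0.10)
  expect_lt(abs(m[2] - 0.73), 0.10)
  expect_lt(abs(m[3] - 0.22), 0.12)
})
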