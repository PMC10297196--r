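#' Configuration for the synthetic nodule cohort generator
#'
#' Bundles every tunable of the synthetic cohort: how many images carry one,
#' two or three nodules, how many patients the images are spread over, the
#' nodule volume distribution, the noise structure linking true volume to the
#' activation-map parameters, the serial-change factors, and the rendering
#' grid. Defaults reproduce the reference cohort: 147 images from 72 patients
#' with a 104/25/18 one/two/three-nodule split (208 nodule observations),
#' volumes with mean 9.37 and SD 11.69 cm^3 truncated to 0.11--70.4 cm^3.
#'
#' The three noise parameters were calibrated once, by simulation, so that the
#' default cohort reproduces the observed Spearman correlation pattern
#' (area--volume ~ 0.58, area--mean probability ~ 0.73, mean
#' probability--volume ~ 0.22); see the package vignette for the calibration
#' procedure and the forward model in which each parameter acts.
#'
#' @param n_images_by_nodule_count Named integer vector: images carrying
#'   `"1"`, `"2"` and `"3"` nodules.
#' @param n_patients Number of patients the images are partitioned into; every
#'   patient receives at least two timepoints (a baseline and one or more
#'   follow-ups).
#' @param volume_mean_mm3,volume_sd_mm3 Target mean and standard deviation of
#'   true nodule volume, in mm^3, of the truncated sampling distribution.
#' @param volume_min_mm3,volume_max_mm3 Truncation bounds, mm^3.
#' @param area_noise_sd SD of the lognormal multiplicative noise on the
#'   projected area (the apparent activation blob is a noisy rendering of the
#'   true cross-section).
#' @param prob_noise_sd SD of the independent Gaussian noise on the latent
#'   probability score.
#' @param prob_vol_decoupling Weight of the true-volume component subtracted
#'   from the latent probability score; larger values decouple mean
#'   probability from true volume while leaving its coupling to apparent area
#'   intact.
#' @param followup_fraction_increase Probability that a serial transition
#'   grows rather than shrinks.
#' @param change_factor_increase,change_factor_decrease Length-2 numeric
#'   ranges of the multiplicative volume-change factor for growing and
#'   shrinking transitions; both are bounded away from 1 so ground-truth
#'   interval-change classes are unambiguous.
#' @param grid_size Length-2 integer vector, probability-map grid in pixels
#'   (rows, columns).
#' @param pixel_spacing_mm Isotropic pixel spacing of the rendered maps,
#'   mm/pixel.
#' @param manufacturer_bias_sd SD of an optional per-image multiplicative bias
#'   on probabilities (log scale), emulating cross-manufacturer
#'   inconsistency. Off (0) by default: the analysis assumes
#'   same-manufacturer serial pairs.
#' @param seed Integer seed driving all sampling in [generate_cohort()].
#'
#' @return A list of class `camvol_cohort_config`.
#' @seealso [generate_cohort()], [sample_volumes()]
#' @export
#' @examples
#' cfg <- cohort_config(seed = 42)
#' cfg$n_images_by_nodule_count
cohort_config <- function(n_images_by_nodule_count = c("1" = 104L, "2" = 25L, "3" = 18L),
                          n_patients = 72L,
                          volume_mean_mm3 = 9370,
                          volume_sd_mm3 = 11690,
                          volume_min_mm3 = 110,
                          volume_max_mm3 = 70400,
                          area_noise_sd = 1.14,
                          prob_noise_sd = 0.64,
                          prob_vol_decoupling = 0.35,
                          followup_fraction_increase = 0.5,
                          change_factor_increase = c(1.3, 2.5),
                          change_factor_decrease = c(0.4, 0.77),
                          grid_size = c(512L, 512L),
                          pixel_spacing_mm = 0.7,
                          manufacturer_bias_sd = 0,
                          seed = 42L) {
  counts <- as.integer(n_images_by_nodule_count)
  names(counts) <- names(n_images_by_nodule_count)
  if (is.null(names(counts)) || !setequal(names(counts), c("1", "2", "3"))) {
    stop("`n_images_by_nodule_count` must be named with \"1\", \"2\", \"3\"", call. = FALSE)
  }
  counts <- counts[c("1", "2", "3")]
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("image counts must be non-negative integers", call. = FALSE)
  }
  if (!(volume_min_mm3 < volume_mean_mm3 && volume_mean_mm3 < volume_max_mm3)) {
    stop("volume bounds must satisfy min < mean < max", call. = FALSE)
  }
  if (volume_sd_mm3 <= 0 || volume_min_mm3 <= 0) {
    stop("volume SD and lower bound must be positive", call. = FALSE)
  }
  stopifnot(
    n_patients >= 0,
    area_noise_sd >= 0, prob_noise_sd >= 0, prob_vol_decoupling >= 0,
    followup_fraction_increase >= 0, followup_fraction_increase <= 1,
    length(change_factor_increase) == 2, all(change_factor_increase > 1),
    length(change_factor_decrease) == 2, all(change_factor_decrease < 1),
    all(change_factor_decrease > 0),
    length(grid_size) == 2, all(grid_size >= 16),
    pixel_spacing_mm > 0, manufacturer_bias_sd >= 0
  )
  structure(
    list(
      n_images_by_nodule_count = counts,
      n_patients = as.integer(n_patients),
      volume_mean_mm3 = volume_mean_mm3,
      volume_sd_mm3 = volume_sd_mm3,
      volume_min_mm3 = volume_min_mm3,
      volume_max_mm3 = volume_max_mm3,
      area_noise_sd = area_noise_sd,
      prob_noise_sd = prob_noise_sd,
      prob_vol_decoupling = prob_vol_decoupling,
      followup_fraction_increase = followup_fraction_increase,
      change_factor_increase = change_factor_increase,
      change_factor_decrease = change_factor_decrease,
      grid_size = as.integer(grid_size),
      pixel_spacing_mm = pixel_spacing_mm,
      manufacturer_bias_sd = manufacturer_bias_sd,
      seed = as.integer(seed)
    ),
    class = "camvol_cohort_config"
  )
}

#' Closed-form lognormal moment matching
#'
#' Returns the (meanlog, sdlog) parameters of the lognormal distribution whose
#' (untruncated) mean and SD equal the arguments:
#' `sdlog^2 = log(1 + (sd/mean)^2)`, `meanlog = log(mean) - sdlog^2 / 2`.
#'
#' @param mean,sd Target mean and standard deviation (same units).
#' @return Named numeric vector `c(meanlog, sdlog)`.
#' @export
#' @examples
#' lognormal_moments(9370, 11690) # meanlog ~ 8.676, sdlog ~ 0.969
lognormal_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Mean and SD of a lognormal truncated to [a, b].
truncated_lognormal_moments <- function(meanlog, sdlog, a, b) {
  al <- (log(a) - meanlog) / sdlog
  be <- (log(b) - meanlog) / sdlog
  z <- pnorm(be) - pnorm(al)
  m1 <- exp(meanlog + sdlog^2 / 2) * (pnorm(be - sdlog) - pnorm(al - sdlog)) / z
  m2 <- exp(2 * meanlog + 2 * sdlog^2) * (pnorm(be - 2 * sdlog) - pnorm(al - 2 * sdlog)) / z
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# Mean and SD of log-volume under the truncated lognormal (truncated normal
# on the log scale); used to standardize the volume signal in the forward
# model for probabilities.
truncated_normal_log_moments <- function(meanlog, sdlog, a, b) {
  al <- (log(a) - meanlog) / sdlog
  be <- (log(b) - meanlog) / sdlog
  z <- pnorm(be) - pnorm(al)
  d <- (dnorm(al) - dnorm(be)) / z
  m <- meanlog + sdlog * d
  v <- sdlog^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z - d^2)
  c(mean = m, sd = sqrt(v))
}

# Calibrate (meanlog, sdlog) so that the TRUNCATED lognormal on
# [volume_min, volume_max] has the requested mean and SD. The printed cohort
# mean/SD describe an observed, range-limited sample, so the generator must
# match them after truncation, not before. Initialized at the closed-form
# untruncated match and solved by Nelder-Mead on relative squared error.
calibrate_truncated_lognormal <- function(mean, sd, a, b) {
  init <- lognormal_moments(mean, sd)
  obj <- function(p) {
    mo <- truncated_lognormal_moments(p[1], exp(p[2]), a, b)
    (mo[["mean"]] - mean)^2 / mean^2 + (mo[["sd"]] - sd)^2 / sd^2
  }
  fit <- optim(c(init[["meanlog"]], log(init[["sdlog"]])), obj,
               control = list(reltol = 1e-14, maxit = 5000))
  if (fit$convergence != 0 || fit$value > 1e-8) {
    stop("could not calibrate the truncated volume distribution to the ",
         "requested mean/SD within the bounds [", a, ", ", b, "]", call. = FALSE)
  }
  c(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
}
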