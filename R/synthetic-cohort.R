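# Synthetic cohort generator: truth tables plus rendered probability maps
# with the statistical structure the volumetry analysis assumes.

# Evaluate code with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Sample true nodule volumes
#'
#' Draws volumes from a lognormal distribution truncated to
#' `[volume_min_mm3, volume_max_mm3]` whose truncated mean and SD equal
#' `volume_mean_mm3` and `volume_sd_mm3` (the parameters are calibrated
#' numerically, starting from the closed-form untruncated match of
#' [lognormal_moments()]). Sampling is by rejection; a fixed `config$seed`
#' yields identical draws.
#'
#' @param config A [cohort_config()].
#' @param n Number of volumes to draw.
#' @return Numeric vector of `n` volumes in mm^3.
#' @export
#' @examples
#' v <- sample_volumes(cohort_config(seed = 1), 5)
sample_volumes <- function(config, n) {
  stopifnot(inherits(config, "camvol_cohort_config"), n >= 0)
  if (n == 0) return(numeric(0))
  with_seed(config$seed, sample_volumes_impl(config, n))
}

sample_volumes_impl <- function(config, n) {
  par <- calibrate_truncated_lognormal(
    config$volume_mean_mm3, config$volume_sd_mm3,
    config$volume_min_mm3, config$volume_max_mm3
  )
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rlnorm(max(2 * (n - length(out)), 16L), par[["meanlog"]], par[["sdlog"]])
    out <- c(out, draw[draw >= config$volume_min_mm3 & draw <= config$volume_max_mm3])
  }
  out[seq_len(n)]
}

# Sphere-equivalent projected radius (mm) of a volume (mm^3).
projected_radius <- function(volume_mm3) (3 * volume_mm3 / (4 * pi))^(1 / 3)

# Partition images into patient series. Every patient gets >= 2 timepoints
# and a constant per-patient nodule multiplicity, so each nodule is observed
# at every one of its patient's timepoints. Returns a data.frame with one row
# per patient: n_nodules, n_timepoints.
allocate_patients <- function(counts, n_patients) {
  ks <- as.integer(names(counts))
  parts <- pmax(counts %/% 2L, ifelse(counts > 0L, 1L, 0L))
  # a multiplicity class with a single image cannot form a >= 2 series
  if (any(counts == 1L)) {
    stop("each nodule-multiplicity class needs 0 or >= 2 images to form serial pairs",
         call. = FALSE)
  }
  total <- sum(parts)
  if (total < n_patients) {
    stop("too many patients for the requested image counts: at most ",
         total, " patients can each receive two timepoints", call. = FALSE)
  }
  # merge series (lengthening follow-up) until the patient count matches,
  # preferring the most numerous class so series stay short
  while (total > n_patients) {
    i <- which.max(ifelse(parts > 1L, counts / parts, -Inf))
    if (parts[i] <= 1L) stop("cannot partition images into ", n_patients, " patients", call. = FALSE)
    parts[i] <- parts[i] - 1L
    total <- total - 1L
  }
  out <- do.call(rbind, lapply(seq_along(ks), function(i) {
    p <- parts[i]
    if (p == 0L) return(NULL)
    len <- rep(counts[i] %/% p, p)
    extra <- counts[i] - sum(len)
    if (extra > 0L) len[seq_len(extra)] <- len[seq_len(extra)] + 1L
    data.frame(n_nodules = ks[i], n_timepoints = len)
  }))
  out[order(-out$n_nodules, -out$n_timepoints), , drop = FALSE]
}

#' Generate a synthetic nodule cohort
#'
#' Builds a full truth table: patients with serial chest images, one to three
#' nodules per image, true CT-reference volumes, and forward-modeled
#' activation-map parameters (projected area and ROI mean probability)
#' carrying the configured noise. Follow-up volumes are baseline volumes
#' multiplied by a change factor drawn from the configured growth/shrinkage
#' ranges, so every serial pair has an unambiguous ground-truth interval
#' change.
#'
#' The forward model per nodule observation: apparent contour radius is the
#' sphere-equivalent projected radius times `exp(e/2)` with
#' `e ~ N(0, area_noise_sd)`, so `area_mm2` is the true cross-section times a
#' lognormal factor; a latent conspicuity score combines the apparent-size
#' signal with a subtracted true-volume component (weight
#' `prob_vol_decoupling`) plus `N(0, prob_noise_sd)` noise; peak probability
#' is a saturating logistic of that score into (0.2, 1], and `prob_mean` is
#' the analytic mean of the rendered Gaussian blob profile over its 0.2
#' contour, `(peak - 0.2) / log(peak / 0.2)`.
#'
#' @param config A [cohort_config()].
#' @return A list of class `camvol_cohort` with elements `nodules` (tibble,
#'   one row per nodule observation: identifiers, timepoint, pixel center,
#'   `true_volume_mm3`, `projected_radius_mm`, `apparent_radius_mm`,
#'   `peak_probability`, `area_mm2`, `prob_mean`) and `images` (tibble, one
#'   row per image: `image_id`, `patient_id`, `timepoint`, `n_nodules`,
#'   `pixel_spacing_mm`).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 42))
#' nrow(coh$nodules) # 208
generate_cohort <- function(config) {
  stopifnot(inherits(config, "camvol_cohort_config"))
  counts <- config$n_images_by_nodule_count
  if (sum(counts) == 0L || config$n_patients == 0L) {
    return(empty_cohort(config))
  }
  with_seed(config$seed, generate_cohort_impl(config))
}

empty_cohort <- function(config) {
  structure(list(
    nodules = tibble::tibble(
      patient_id = character(), nodule_id = character(), image_id = character(),
      timepoint = integer(), nodule_index = integer(),
      center_row = integer(), center_col = integer(),
      true_volume_mm3 = numeric(), projected_radius_mm = numeric(),
      apparent_radius_mm = numeric(), peak_probability = numeric(),
      area_mm2 = numeric(), prob_mean = numeric()
    ),
    images = tibble::tibble(
      image_id = character(), patient_id = character(), timepoint = integer(),
      n_nodules = integer(), pixel_spacing_mm = numeric()
    ),
    config = config
  ), class = "camvol_cohort")
}

generate_cohort_impl <- function(config) {
  plan <- allocate_patients(config$n_images_by_nodule_count, config$n_patients)
  plan$patient_id <- sprintf("P%03d", seq_len(nrow(plan)))

  par <- calibrate_truncated_lognormal(config$volume_mean_mm3, config$volume_sd_mm3,
                                       config$volume_min_mm3, config$volume_max_mm3)
  logm <- truncated_normal_log_moments(par[["meanlog"]], par[["sdlog"]],
                                       config$volume_min_mm3, config$volume_max_mm3)

  # baseline volume per unique nodule, in patient order
  n_unique <- sum(plan$n_nodules)
  v0 <- sample_volumes_impl(config, n_unique)

  rows <- vector("list", nrow(plan))
  idx <- 0L
  for (p in seq_len(nrow(plan))) {
    np <- plan$n_nodules[p]
    nt <- plan$n_timepoints[p]
    vols <- matrix(NA_real_, nrow = np, ncol = nt)
    vols[, 1] <- v0[idx + seq_len(np)]
    idx <- idx + np
    for (t in 2:nt) {
      for (j in seq_len(np)) {
        vols[j, t] <- step_volume(vols[j, t - 1], config)
      }
    }
    rows[[p]] <- tibble::tibble(
      patient_id = plan$patient_id[p],
      nodule_index = rep(seq_len(np), times = nt),
      timepoint = rep(seq_len(nt) - 1L, each = np),
      true_volume_mm3 = as.vector(vols)
    )
  }
  nod <- dplyr::bind_rows(rows)
  nod$nodule_id <- sprintf("%s-N%d", nod$patient_id, nod$nodule_index)
  nod$image_id <- sprintf("%s-T%d", nod$patient_id, nod$timepoint)
  nod$projected_radius_mm <- projected_radius(nod$true_volume_mm3)

  # forward-model the activation-map parameters
  n <- nrow(nod)
  e_area <- rnorm(n, 0, config$area_noise_sd)
  eta <- rnorm(n, 0, 1)
  nod$apparent_radius_mm <- nod$projected_radius_mm * exp(e_area / 2)
  nod$area_mm2 <- pi * nod$apparent_radius_mm^2

  z_vol <- (log(nod$true_volume_mm3) - logm[["mean"]]) / logm[["sd"]]
  sd_logarea <- sqrt(((2 / 3) * logm[["sd"]])^2 + config$area_noise_sd^2)
  z_app <- ((2 / 3) * logm[["sd"]] * z_vol + e_area) / sd_logarea
  latent <- z_app - config$prob_vol_decoupling * z_vol + config$prob_noise_sd * eta
  if (config$manufacturer_bias_sd > 0) {
    img_ids <- unique(nod$image_id)
    bias <- setNames(rnorm(length(img_ids), 0, config$manufacturer_bias_sd), img_ids)
    latent <- latent + bias[nod$image_id]
  }
  nod$peak_probability <- 0.2 + 0.8 * plogis(0.5 + latent)
  nod$prob_mean <- blob_mean_probability(nod$peak_probability)

  # place nodules on the grid, image by image
  nod$center_row <- NA_integer_
  nod$center_col <- NA_integer_
  for (img in unique(nod$image_id)) {
    sel <- which(nod$image_id == img)
    ctr <- place_nodules(nod$apparent_radius_mm[sel], config)
    nod$center_row[sel] <- ctr[, 1]
    nod$center_col[sel] <- ctr[, 2]
  }

  nod <- nod[, c("patient_id", "nodule_id", "image_id", "timepoint", "nodule_index",
                 "center_row", "center_col", "true_volume_mm3", "projected_radius_mm",
                 "apparent_radius_mm", "peak_probability", "area_mm2", "prob_mean")]
  images <- dplyr::distinct(nod[, c("image_id", "patient_id", "timepoint")])
  images$n_nodules <- as.integer(table(nod$image_id)[images$image_id])
  images$pixel_spacing_mm <- config$pixel_spacing_mm

  structure(list(nodules = nod, images = tibble::as_tibble(images), config = config),
            class = "camvol_cohort")
}

# Analytic mean of a Gaussian blob profile with the given peak over its 0.2
# iso-contour: (peak - c) / log(peak / c) with c = 0.2.
blob_mean_probability <- function(peak, cutoff = 0.2) {
  (peak - cutoff) / log(peak / cutoff)
}

# One serial volume transition: multiplicative factor, direction sampled by
# followup_fraction_increase, flipped if the result leaves the volume bounds.
step_volume <- function(v, config) {
  up <- runif(1) < config$followup_fraction_increase
  f_up <- runif(1, config$change_factor_increase[1], config$change_factor_increase[2])
  f_dn <- runif(1, config$change_factor_decrease[1], config$change_factor_decrease[2])
  v1 <- v * if (up) f_up else f_dn
  if (v1 > config$volume_max_mm3 || v1 < config$volume_min_mm3) {
    v1 <- v * if (up) f_dn else f_up
  }
  min(max(v1, config$volume_min_mm3), config$volume_max_mm3)
}

# Rejection-sample nodule centers (pixel row/col) with all 0.2 contours inside
# the grid and centers separated by at least 2 x (sum of contour radii),
# relaxed to 1.2 x after repeated failure. Extreme area-noise draws can make a
# blob larger than the grid allows; the margin is then clamped (the contour
# clips at the edge) and, if no separated configuration exists, the
# best-separated configuration seen is kept, with a warning in both cases.
place_nodules <- function(radii_mm, config) {
  r_px <- radii_mm / config$pixel_spacing_mm
  nr <- config$grid_size[1]; nc <- config$grid_size[2]
  margin <- ceiling(r_px) + 2
  cap <- floor((min(nr, nc) - 4) / 2)
  if (any(margin > cap)) {
    warning("nodule contour radius ", signif(max(radii_mm), 3),
            " mm exceeds the grid; contour will clip at the edge")
    margin <- pmin(margin, cap)
  }
  min_ratio <- function(ctr, relax) {
    if (length(r_px) < 2) return(Inf)
    worst <- Inf
    for (i in seq_len(length(r_px) - 1)) {
      for (j in (i + 1):length(r_px)) {
        d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
        worst <- min(worst, d / (r_px[i] + r_px[j]))
      }
    }
    worst
  }
  best <- NULL
  best_ratio <- -Inf
  for (relax in c(2, 1.2)) {
    for (attempt in seq_len(500)) {
      ctr <- cbind(
        row = floor(runif(length(r_px), margin + 1, nr - margin)),
        col = floor(runif(length(r_px), margin + 1, nc - margin))
      )
      ratio <- min_ratio(ctr, relax)
      if (ratio >= relax) return(ctr)
      if (ratio > best_ratio) {
        best <- ctr
        best_ratio <- ratio
      }
    }
  }
  warning("could not separate ", length(r_px), " nodule contours ",
          "(best separation ", signif(best_ratio, 3),
          " x the contact distance); keeping the best configuration")
  best
}

#' Render a probability map for a set of nodules
#'
#' Draws each nodule as a radially decreasing Gaussian blob with the stated
#' peak probability, scaled so the 0.2 iso-contour radius equals the nodule's
#' apparent (area-noise-adjusted) contour radius. The background is zero and
#' overlapping tails combine by maximum, so all values stay in \[0, 1\].
#'
#' @param nodules A tibble of nodule truth rows (typically one image's rows of
#'   `generate_cohort(...)$nodules`) with columns `center_row`, `center_col`,
#'   `peak_probability`, `apparent_radius_mm`.
#' @param config A [cohort_config()] supplying grid size and pixel spacing.
#' @param image_id Identifier attached to the returned map.
#' @return A [probability_map()].
#' @export
#' @examples
#' cfg <- cohort_config(grid_size = c(64, 64), pixel_spacing_mm = 1, seed = 1)
#' nod <- tibble::tibble(center_row = 32, center_col = 32,
#'                       peak_probability = 0.8, apparent_radius_mm = 10)
#' m <- render_probability_map(nod, cfg)
#' sum(m$values > 0.2) # ~ pi * 10^2
render_probability_map <- function(nodules, config, image_id = "synthetic") {
  stopifnot(inherits(config, "camvol_cohort_config"))
  nr <- config$grid_size[1]; nc <- config$grid_size[2]
  vals <- matrix(0, nr, nc)
  if (nrow(nodules) > 0) {
    if (any(nodules$center_row < 1 | nodules$center_row > nr |
            nodules$center_col < 1 | nodules$center_col > nc)) {
      stop("placement error: nodule center outside the grid", call. = FALSE)
    }
    for (i in seq_len(nrow(nodules))) {
      peak <- nodules$peak_probability[i]
      stopifnot(peak > 0.2, peak <= 1)
      r_px <- nodules$apparent_radius_mm[i] / config$pixel_spacing_mm
      s2 <- r_px^2 / (2 * log(peak / 0.2))
      # evaluate only within the radius where the tail falls below 0.005
      ext <- ceiling(sqrt(2 * s2 * log(peak / 0.005)))
      r0 <- max(1L, nodules$center_row[i] - ext); r1 <- min(nr, nodules$center_row[i] + ext)
      c0 <- max(1L, nodules$center_col[i] - ext); c1 <- min(nc, nodules$center_col[i] + ext)
      dr <- (r0:r1) - nodules$center_row[i]
      dc <- (c0:c1) - nodules$center_col[i]
      d2 <- outer(dr^2, dc^2, "+")
      blob <- peak * exp(-d2 / (2 * s2))
      vals[r0:r1, c0:c1] <- pmax(vals[r0:r1, c0:c1], blob)
    }
  }
  probability_map(pmin(vals, 1), config$pixel_spacing_mm, image_id = image_id)
}
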