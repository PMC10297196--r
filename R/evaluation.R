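# Cohort-level statistics: Spearman correlations, the six-way model
# comparison by training RMSE, and residual diagnostics.

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (via
#' `stats::cor(method = "spearman")`). Constant input is rejected rather than
#' returned as `NA`.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return Correlation in \[-1, 1\].
#' @export
#' @examples
#' spearman_rho(1:4, c(2, 1, 4, 3)) # 0.6
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("rank correlation is undefined for a constant vector", call. = FALSE)
  }
  cor(x, y, method = "spearman")
}

#' Compare volume models across degrees and variable sets
#'
#' Fits every requested (degree, variable-set) combination on the cohort and
#' reports the training RMSE — the comparison the method uses for model
#' selection (no held-out split: the reference analysis performed no internal
#' validation). For context each row also carries the Spearman correlation
#' between area and volume and the R^2 of the fit.
#'
#' @param cohort Tibble with columns `area_mm2`, `prob_mean`,
#'   `true_volume_mm3` and at least 20 complete rows.
#' @param degrees Degrees to fit (subset of 1, 1.5, 2).
#' @param variable_sets Variable sets to fit (subset of `"area"`,
#'   `"area+prob"`).
#' @return A tibble of class `camvol_model_comparison`: `degree`,
#'   `variables`, `n_terms`, `rmse`, `spearman_area_vol`, `r_squared`,
#'   `error` (message for combinations with a singular fit, else `NA`), plus
#'   the fitted `camvol_fit` objects in `attr(, "fits")` (named
#'   `"<degree>/<variables>"`). `n_obs` is carried in `attr(, "n_obs")`.
#' @export
compare_models <- function(cohort,
                           degrees = c(1, 1.5, 2),
                           variable_sets = c("area", "area+prob")) {
  keep <- stats::complete.cases(cohort[, c("area_mm2", "prob_mean", "true_volume_mm3")])
  cohort <- cohort[keep, ]
  if (nrow(cohort) < 20) {
    stop("model comparison needs at least 20 nodules with valid ",
         "(area, probability, volume)", call. = FALSE)
  }
  cohort <- cohort[order(cohort$area_mm2, cohort$prob_mean, cohort$true_volume_mm3), ]
  rho_av <- spearman_rho(cohort$area_mm2, cohort$true_volume_mm3)
  grid <- expand.grid(degree = degrees, variables = variable_sets,
                      stringsAsFactors = FALSE)
  fits <- list()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- basis_spec(grid$degree[i], grid$variables[i])
    key <- sprintf("%g/%s", spec$degree, spec$variables)
    fit <- tryCatch(fit_volume_model(cohort, spec), error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble::tibble(degree = spec$degree, variables = spec$variables,
                            n_terms = nrow(basis_terms(spec)), rmse = NA_real_,
                            spearman_area_vol = rho_av, r_squared = NA_real_,
                            error = conditionMessage(fit)))
    }
    fits[[key]] <<- fit
    ssr <- sum(fit$residuals^2)
    sst <- sum((cohort$true_volume_mm3 - mean(cohort$true_volume_mm3))^2)
    tibble::tibble(degree = spec$degree, variables = spec$variables,
                   n_terms = length(fit$model$coefficients), rmse = fit$rmse,
                   spearman_area_vol = rho_av, r_squared = 1 - ssr / sst,
                   error = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  attr(out, "n_obs") <- nrow(cohort)
  class(out) <- c("camvol_model_comparison", class(out))
  out
}

#' Per-observation residual table
#'
#' Joins a fit's residuals (observed minus predicted volume, mm^3) back to
#' nodule identity, and counts residuals beyond 40,000 mm^3 in magnitude —
#' the outlier region flagged in the reference analysis, where a handful of
#' large masses dominate the error.
#'
#' @param fit A `camvol_fit` from [fit_volume_model()] or [fit_ols()].
#' @param cohort The cohort tibble the model was fitted on (same row order
#'   and length as the fit).
#' @param outlier_mm3 Magnitude above which a residual counts as an outlier.
#' @return A tibble with identifier columns (any of `patient_id`,
#'   `nodule_id`, `image_id`, `timepoint` present in `cohort`), `observed`,
#'   `predicted` and `residual` (mm^3); the outlier count is in
#'   `attr(, "n_outliers")`.
#' @export
residual_table <- function(fit, cohort, outlier_mm3 = 40000) {
  stopifnot(inherits(fit, "camvol_fit"))
  if (nrow(cohort) != fit$n_obs) {
    stop("cohort (", nrow(cohort), " rows) is not aligned with the fit (",
         fit$n_obs, " observations)", call. = FALSE)
  }
  ids <- intersect(c("patient_id", "nodule_id", "image_id", "timepoint"),
                   names(cohort))
  out <- tibble::as_tibble(cohort[, ids])
  out$observed <- cohort$true_volume_mm3
  out$predicted <- cohort$true_volume_mm3 - fit$residuals
  out$residual <- fit$residuals
  attr(out, "n_outliers") <- sum(abs(out$residual) > outlier_mm3)
  out
}
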