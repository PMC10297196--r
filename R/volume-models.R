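# Polynomial volume-prediction models on (area, mean probability), including
# the published fitted equations as frozen constants.
#
# The degree-1.5 ("unit-adjusted") family exists because a projected area
# (mm^2) raised to the power 1.5 has the units of a volume (mm^3); its basis
# is the complete cubic in the square roots of area and mean probability.

#' Basis specification for a volume model
#'
#' @param degree One of 1, 1.5 or 2.
#' @param variables `"area"` (univariable) or `"area+prob"` (multivariable).
#' @return A list of class `camvol_basis_spec`.
#' @export
#' @examples
#' basis_spec(1.5, "area+prob")
basis_spec <- function(degree, variables = c("area+prob", "area")) {
  if (!degree %in% c(1, 1.5, 2)) {
    stop("unsupported degree ", degree, ": must be 1, 1.5 or 2", call. = FALSE)
  }
  variables <- match.arg(variables)
  structure(list(degree = degree, variables = variables), class = "camvol_basis_spec")
}

#' Basis terms of a model specification
#'
#' Enumerates the monomials `Area^e1 * Prob^e2` of the basis. Integer degrees
#' use ordinary polynomial terms of total degree up to the degree; degree 1.5
#' uses every half-integer monomial `(A^0.5)^i (P^0.5)^j` with `i + j <= 3`
#' (10 terms multivariable, 4 univariable) — the complete cubic in the square
#' roots, which is exactly the term set of the published unit-adjusted
#' equation. Ordering is fixed: ascending total degree, higher area power
#' first within a level.
#'
#' @param spec A [basis_spec()].
#' @return Numeric matrix with columns `exp_area`, `exp_prob`, one row per
#'   term.
#' @export
#' @examples
#' basis_terms(basis_spec(1, "area+prob")) # intercept, A, P
basis_terms <- function(spec) {
  stopifnot(inherits(spec, "camvol_basis_spec"))
  step <- if (spec$degree == 1.5) 0.5 else 1
  total <- if (spec$degree == 1.5) 1.5 else spec$degree
  levels <- seq(0, total, by = step)
  rows <- list()
  for (lev in levels) {
    ea <- seq(lev, 0, by = -step)
    for (a in ea) {
      p <- lev - a
      if (spec$variables == "area" && p > 0) next
      rows[[length(rows) + 1L]] <- c(a, p)
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("exp_area", "exp_prob")
  m
}

#' Design matrix for a basis specification
#'
#' @param area_mm2 Numeric vector of ROI areas (mm^2), strictly positive.
#' @param prob_mean Numeric vector of ROI mean probabilities in (0, 1\].
#' @param spec A [basis_spec()].
#' @return Matrix with one row per observation and one column per basis term
#'   (column order of [basis_terms()]).
#' @export
design_matrix <- function(area_mm2, prob_mean, spec) {
  stopifnot(length(area_mm2) == length(prob_mean))
  if (any(area_mm2 <= 0)) {
    stop("non-positive area is outside the model domain (fractional powers)",
         call. = FALSE)
  }
  if (any(prob_mean <= 0 | prob_mean > 1)) {
    stop("mean probability must lie in (0, 1]", call. = FALSE)
  }
  tm <- basis_terms(spec)
  X <- vapply(seq_len(nrow(tm)), function(i) area_mm2^tm[i, 1] * prob_mean^tm[i, 2],
              numeric(length(area_mm2)))
  X <- matrix(X, nrow = length(area_mm2))
  colnames(X) <- term_labels(tm)
  X
}

term_labels <- function(tm) {
  apply(tm, 1, function(e) {
    if (e[1] == 0 && e[2] == 0) return("1")
    parts <- c(
      if (e[1] > 0) sprintf("A^%g", e[1]),
      if (e[2] > 0) sprintf("P^%g", e[2])
    )
    paste(parts, collapse = "*")
  })
}

#' Construct a volume model
#'
#' @param spec A [basis_spec()].
#' @param coefficients Numeric vector, one coefficient per basis term in
#'   [basis_terms()] order; units such that predictions are mm^3.
#' @param provenance `"fitted"` or `"published"`.
#' @return A list of class `camvol_model`.
#' @export
volume_model <- function(spec, coefficients, provenance = c("fitted", "published")) {
  stopifnot(inherits(spec, "camvol_basis_spec"))
  tm <- basis_terms(spec)
  if (length(coefficients) != nrow(tm)) {
    stop("coefficient count (", length(coefficients), ") does not match the ",
         nrow(tm), "-term basis", call. = FALSE)
  }
  structure(list(spec = spec, terms = tm,
                 coefficients = as.numeric(coefficients),
                 provenance = match.arg(provenance)),
            class = "camvol_model")
}

#' @export
print.camvol_model <- function(x, ...) {
  cat(sprintf("<volume model: degree %g, %s, %d terms, %s>\n",
              x$spec$degree, x$spec$variables, length(x$coefficients), x$provenance))
  print(setNames(x$coefficients, term_labels(x$terms)))
  invisible(x)
}

#' Predict nodule volume from activation-map parameters
#'
#' @param model A [volume_model()].
#' @param area_mm2,prob_mean Parameter vectors (recycled to common length for
#'   univariable models where `prob_mean` is ignored but still validated).
#' @param clamp_zero If `TRUE`, negative predictions (possible under cubic
#'   extrapolation outside the calibration range) are clamped to 0. Off by
#'   default.
#' @return Predicted volumes in mm^3.
#' @export
#' @examples
#' predict_volume(published_model_15(), 761.6, 0.514) / 1000 # ~ 8.50 cm^3
predict_volume <- function(model, area_mm2, prob_mean, clamp_zero = FALSE) {
  stopifnot(inherits(model, "camvol_model"))
  X <- design_matrix(area_mm2, prob_mean, model$spec)
  out <- drop(X %*% model$coefficients)
  if (clamp_zero) out <- pmax(out, 0)
  out
}

#' Ordinary least-squares fit of a volume model
#'
#' Minimizes the residual sum of squares of `y - X beta`. The basis columns
#' span many orders of magnitude (an `A^1.5` column reaches 10^5 while `P^1.5`
#' stays below 1), so each column is scaled to unit maximum absolute value
#' before the QR solve and the coefficients are rescaled afterwards; the
#' result is the exact least-squares solution of the original problem.
#'
#' @param X Design matrix from [design_matrix()].
#' @param y Reference volumes, mm^3.
#' @param spec The [basis_spec()] that generated `X` (stored in the model).
#' @return A list of class `camvol_fit`: `model` ([volume_model()]),
#'   `residuals` (mm^3), `rmse` (mm^3), `n_obs`.
#' @export
fit_ols <- function(X, y, spec) {
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < ncol(X)) {
    stop("fewer observations (", nrow(X), ") than basis terms (", ncol(X), ")",
         call. = FALSE)
  }
  scale <- apply(abs(X), 2, max)
  scale[scale == 0] <- 1
  Xs <- sweep(X, 2, scale, "/")
  qr_xs <- qr(Xs)
  if (qr_xs$rank < ncol(Xs)) {
    bad <- colnames(X)[qr_xs$pivot[(qr_xs$rank + 1):ncol(Xs)]]
    stop("singular fit: column(s) ", paste(bad, collapse = ", "),
         " are linearly dependent after scaling", call. = FALSE)
  }
  beta <- qr.coef(qr_xs, y) / scale
  res <- y - drop(X %*% beta)
  list(
    model = volume_model(spec, beta, "fitted"),
    residuals = res,
    rmse = sqrt(mean(res^2)),
    n_obs = length(y)
  ) |> structure(class = "camvol_fit")
}

#' Fit a volume model to a cohort table
#'
#' Convenience wrapper building the design matrix from cohort columns
#' `area_mm2`, `prob_mean`, `true_volume_mm3` and calling [fit_ols()].
#'
#' @param cohort Tibble with columns `area_mm2`, `prob_mean`,
#'   `true_volume_mm3`.
#' @param spec A [basis_spec()].
#' @return A `camvol_fit` (see [fit_ols()]).
#' @export
fit_volume_model <- function(cohort, spec) {
  X <- design_matrix(cohort$area_mm2, cohort$prob_mean, spec)
  fit_ols(X, cohort$true_volume_mm3, spec)
}

#' The published unit-adjusted (degree-1.5) multivariable model
#'
#' The frozen coefficients of the reported best model, a complete cubic in
#' (sqrt(Area), sqrt(Mean probability)) mapping mm^2 and probability to mm^3.
#' Two term labels in the printed equation are garbled duplicates; they are
#' resolved as the `Area^1.5` and `Mean probability^1.5` terms, the only
#' monomials of the complete half-power basis not otherwise present — a
#' reading confirmed by reproducing both printed worked-example predictions
#' (8.50 and 16.35 cm^3) to within rounding.
#'
#' @return A [volume_model()] with provenance `"published"`.
#' @export
#' @examples
#' predict_volume(published_model_15(), 1079.6, 0.529) / 1000 # ~ 16.35
published_model_15 <- function() {
  volume_model(
    basis_spec(1.5, "area+prob"),
    c(578437.473048,      # 1
      52661.249342,       # A^0.5
      -4508167.245662,    # P^0.5
      826.73901,          # A
      -217913.487756,     # A^0.5 * P^0.5
      10744046.813175,    # P
      -3.158884,          # A^1.5
      -804.666435,        # A * P^0.5
      191918.949126,      # A^0.5 * P
      -7729391.963889),   # P^1.5
    provenance = "published"
  )
}

#' The published linear-plane model
#'
#' The reported degree-1 multivariable fit:
#' `Volume = 14886.637214 + 29.288656 * Area - 57206.109259 * Mean probability`.
#'
#' @return A [volume_model()] with provenance `"published"`.
#' @export
published_plane <- function() {
  volume_model(
    basis_spec(1, "area+prob"),
    c(14886.637214, 29.288656, -57206.109259),
    provenance = "published"
  )
}

#' Write / read a volume model as JSON
#'
#' The file stores the basis (degree, variable set, ordered exponent pairs),
#' the coefficient vector at full double precision, and the provenance;
#' a write/read round trip reproduces the coefficients bit-exactly.
#'
#' @param model A [volume_model()].
#' @param path File path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns the [volume_model()].
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "camvol_model"))
  obj <- list(
    basis = list(degree = model$spec$degree, variables = model$spec$variables,
                 terms = unname(apply(model$terms, 1, as.numeric, simplify = FALSE))),
    coefficients = model$coefficients,
    provenance = model$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- basis_spec(obj$basis$degree, obj$basis$variables)
  model <- volume_model(spec, obj$coefficients, obj$provenance)
  stored <- obj$basis$terms
  if (is.list(stored)) stored <- do.call(rbind, stored)
  stored <- matrix(as.numeric(stored), ncol = 2)
  if (!isTRUE(all.equal(unname(model$terms), unname(stored)))) {
    stop("stored basis terms do not match the ", obj$basis$degree,
         "-degree basis", call. = FALSE)
  }
  model
}
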