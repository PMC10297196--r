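# Thresholding of probability maps, ROI extraction and the five per-ROI
# parameters: area, weighted opacity-area product, mean/median/max probability.

#' Construct a probability map
#'
#' A probability map is the per-pixel lesion-probability surface a detection
#' network emits for one radiograph (its class-activation map), together with
#' the physical pixel spacing needed to express areas in mm^2.
#'
#' @param values Numeric matrix with entries in \[0, 1\]; rows are image rows
#'   (origin top-left).
#' @param pixel_spacing_mm Isotropic pixel spacing, mm/pixel. Anisotropic
#'   spacing (a length-2 vector with unequal entries) is rejected rather than
#'   silently averaged.
#' @param image_id Optional identifier.
#' @param manufacturer_tag Optional scanner-manufacturer label.
#' @return An object of class `camvol_probability_map`.
#' @export
#' @examples
#' m <- probability_map(matrix(runif(100), 10, 10), pixel_spacing_mm = 0.7)
probability_map <- function(values, pixel_spacing_mm, image_id = NA_character_,
                            manufacturer_tag = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values) || length(values) == 0) {
    stop("`values` must be a non-empty numeric matrix", call. = FALSE)
  }
  if (anyNA(values) || min(values) < 0 || max(values) > 1) {
    stop("probability values must lie in [0, 1] with no missing entries", call. = FALSE)
  }
  if (length(pixel_spacing_mm) == 2) {
    if (abs(pixel_spacing_mm[1] - pixel_spacing_mm[2]) > 1e-9) {
      stop("anisotropic pixel spacing is not supported", call. = FALSE)
    }
    pixel_spacing_mm <- pixel_spacing_mm[1]
  }
  stopifnot(length(pixel_spacing_mm) == 1, pixel_spacing_mm > 0)
  structure(list(values = values, pixel_spacing_mm = pixel_spacing_mm,
                 image_id = image_id, manufacturer_tag = manufacturer_tag),
            class = "camvol_probability_map")
}

#' @export
print.camvol_probability_map <- function(x, ...) {
  cat(sprintf("<probability map %s: %d x %d px, %.3g mm/px, max p = %.3f>\n",
              x$image_id, nrow(x$values), ncol(x$values),
              x$pixel_spacing_mm, max(x$values)))
  invisible(x)
}

#' Image-level positivity
#'
#' An image is called positive when its image-level probability score reaches
#' the binary-classification threshold (default 15%). The detector's own
#' image-level score is not part of the map, so the maximum pixel probability
#' serves as its surrogate; the boundary is inclusive (score equal to the
#' threshold is positive).
#'
#' @param map A [probability_map()].
#' @param threshold Positivity threshold in \[0, 1\].
#' @return `TRUE` or `FALSE`.
#' @export
image_positive <- function(map, threshold = 0.15) {
  stopifnot(inherits(map, "camvol_probability_map"),
            threshold >= 0, threshold <= 1)
  max(map$values) >= threshold
}

#' Threshold a probability map
#'
#' Returns the binary lesion mask at the ROI cutoff. The inequality is
#' strict: a pixel exactly at the cutoff is background, so a uniform map at
#' the cutoff yields an empty mask.
#'
#' @param map A [probability_map()].
#' @param cutoff ROI probability cutoff in (0, 1); default 0.2.
#' @return Logical matrix of the same shape as the map.
#' @export
threshold_mask <- function(map, cutoff = 0.2) {
  stopifnot(inherits(map, "camvol_probability_map"), cutoff > 0, cutoff < 1)
  map$values > cutoff
}

# Label 8-connected components of a logical mask. Foreground pixels become
# vertices of the pixel-adjacency graph (edges between 8-neighbours) and
# components are read off with igraph. Returns an integer matrix, 0 for
# background, 1..k arbitrary component labels.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask)
  if (length(fg) == 0) return(lab)
  rank <- integer(length(mask))
  rank[fg] <- seq_along(fg)
  nr <- nrow(mask)
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  edges <- list()
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- rr + sh[1]; c2 <- cc + sh[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    both <- mask[nb]
    edges[[length(edges) + 1L]] <- cbind(rank[fg[ok][both]], rank[nb[both]])
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  lab[fg] <- igraph::components(g)$membership
  lab
}

#' Weighted opacity-area product of an ROI
#'
#' The WOAP of a region is its probability-weighted area: the sum over ROI
#' pixels of the pixel probability times the pixel area, i.e. the integral of
#' the probability surface over the region, in mm^2. It reduces to the plain
#' area when the probability is 1 everywhere in the ROI.
#'
#' @param pixels Integer vector of linear pixel indices into the map.
#' @param map A [probability_map()].
#' @return WOAP in mm^2.
#' @export
compute_woap <- function(pixels, map) {
  stopifnot(inherits(map, "camvol_probability_map"))
  if (length(pixels) == 0) stop("WOAP of an empty ROI is undefined", call. = FALSE)
  sum(map$values[pixels]) * map$pixel_spacing_mm^2
}

#' Extract regions of interest from a probability map
#'
#' Thresholds the map at `cutoff` (strict), labels 8-connected components,
#' orders them by descending area and keeps at most `max_rois` (mirroring the
#' up-to-three-nodules-per-image reading convention). For each ROI the five
#' parameters are computed: area (mm^2), weighted opacity-area product
#' (mm^2), and mean, median and maximum probability. Area ties break by
#' descending maximum probability, then by row-major centroid order, so the
#' output ordering is deterministic.
#'
#' @param map A [probability_map()].
#' @param cutoff ROI probability cutoff; default 0.2.
#' @param max_rois Maximum number of ROIs returned; default 3.
#' @return A tibble with one row per ROI: `roi_id`, `pixel_count`,
#'   `area_mm2`, `woap`, `prob_mean`, `prob_median`, `prob_max`,
#'   `centroid_row`, `centroid_col`. Zero rows if no pixel exceeds the
#'   cutoff.
#' @export
#' @examples
#' m <- probability_map(matrix(1, 10, 10), 1)
#' extract_rois(m) # one ROI, area 100 mm^2
extract_rois <- function(map, cutoff = 0.2, max_rois = 3) {
  stopifnot(inherits(map, "camvol_probability_map"), max_rois >= 1)
  lab <- label_components(threshold_mask(map, cutoff))
  ids <- setdiff(unique(as.vector(lab)), 0L)
  empty <- tibble::tibble(
    roi_id = integer(), pixel_count = integer(), area_mm2 = numeric(),
    woap = numeric(), prob_mean = numeric(), prob_median = numeric(),
    prob_max = numeric(), centroid_row = numeric(), centroid_col = numeric()
  )
  if (length(ids) == 0) return(empty)
  sp2 <- map$pixel_spacing_mm^2
  nr <- nrow(map$values)
  rois <- lapply(ids, function(id) {
    px <- which(lab == id)
    p <- map$values[px]
    tibble::tibble(
      pixel_count = length(px),
      area_mm2 = length(px) * sp2,
      woap = sum(p) * sp2,
      prob_mean = mean(p),
      prob_median = median(p),
      prob_max = max(p),
      centroid_row = mean(((px - 1L) %% nr) + 1L),
      centroid_col = mean(((px - 1L) %/% nr) + 1L)
    )
  })
  out <- dplyr::bind_rows(rois)
  ord <- order(-out$area_mm2, -out$prob_max, out$centroid_row, out$centroid_col)
  out <- out[head(ord, max_rois), ]
  out$roi_id <- seq_len(nrow(out))
  out[, c("roi_id", "pixel_count", "area_mm2", "woap", "prob_mean",
          "prob_median", "prob_max", "centroid_row", "centroid_col")]
}

#' Match extracted ROIs to ground-truth nodules
#'
#' Greedy nearest-centroid assignment: the globally closest (ROI, nodule)
#' pair is matched first, both are removed, and the process repeats. A match
#' is only accepted within a per-nodule distance gate (default twice the
#' nodule's contour radius); ROIs left without a nodule map to `NA`.
#'
#' @param rois Tibble from [extract_rois()] (`centroid_row`, `centroid_col`).
#' @param truths Tibble of nodule truth rows (`nodule_id`, `center_row`,
#'   `center_col`, `apparent_radius_mm`).
#' @param pixel_spacing_mm Spacing used to express distances in mm.
#' @param gate_factor Gate radius as a multiple of the nodule contour radius.
#' @return Character vector along `rois` rows: matched `nodule_id` or `NA`.
#' @export
match_rois_to_nodules <- function(rois, truths, pixel_spacing_mm, gate_factor = 2) {
  out <- rep(NA_character_, nrow(rois))
  if (nrow(rois) == 0 || nrow(truths) == 0) return(out)
  d <- outer(seq_len(nrow(rois)), seq_len(nrow(truths)), function(i, j) {
    sqrt((rois$centroid_row[i] - truths$center_row[j])^2 +
         (rois$centroid_col[i] - truths$center_col[j])^2) * pixel_spacing_mm
  })
  gate <- matrix(gate_factor * truths$apparent_radius_mm,
                 nrow(rois), nrow(truths), byrow = TRUE)
  d[d > gate] <- Inf
  while (any(is.finite(d))) {
    k <- arrayInd(which.min(d), dim(d))
    out[k[1]] <- truths$nodule_id[k[2]]
    d[k[1], ] <- Inf
    d[, k[2]] <- Inf
  }
  out
}
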