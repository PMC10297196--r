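test_that("image positivity uses the inclusive 15% boundary", {
  expect_false(image_positive(probability_map(matrix(0.10, 4, 4), 1)))
  m <- matrix(0, 4, 4); m[2, 2] <- 0.5
  expect_true(image_positive(probability_map(m, 1)))
  m2 <- matrix(0, 4, 4); m2[1, 1] <- 0.15
  expect_true(image_positive(probability_map(m2, 1)))
})

test_that("the ROI mask uses a strict cutoff", {
  expect_false(any(threshold_mask(probability_map(matrix(0, 4, 4), 1))))
  expect_false(any(threshold_mask(probability_map(matrix(0.2, 4, 4), 1))))
  expect_true(all(threshold_mask(probability_map(matrix(0.21, 4, 4), 1))))
})

test_that("uniform and two-blob maps yield the expected ROI parameters", {
  expect_equal(nrow(extract_rois(probability_map(matrix(0, 8, 8), 1))), 0)

  u <- extract_rois(probability_map(matrix(1, 10, 10), 1))
  expect_equal(u$pixel_count, 100)
  expect_equal(u$area_mm2, 100)
  expect_equal(u$woap, 100)
  expect_equal(c(u$prob_mean, u$prob_median, u$prob_max), c(1, 1, 1))

  # two separated 4-pixel blobs, p = 0.5 and p = 0.9, spacing 2 mm
  v <- matrix(0, 6, 6)
  v[1:2, 1:2] <- 0.5
  v[5:6, 5:6] <- 0.9
  m <- probability_map(v, 2)
  rois <- extract_rois(m)
  expect_equal(nrow(rois), 2)
  expect_equal(rois$area_mm2, c(16, 16))
  # equal areas: tie broken by descending max probability
  expect_equal(rois$prob_max, c(0.9, 0.5))
  orc <- oracle_roi_params(v, 2)
  orc <- orc[order(-orc$area_mm2, -orc$prob_max), ]
  for (col in c("pixel_count", "area_mm2", "woap", "prob_mean", "prob_median",
                "prob_max", "centroid_row", "centroid_col")) {
    expect_equal(rois[[col]], orc[[col]], ignore_attr = TRUE)
  }
})

test_that("extraction matches the flood-fill oracle on random maps", {
  set.seed(71)
  for (i in 1:20) {
    m <- random_blob_map(32, spacing = runif(1, 0.5, 2))
    rois <- extract_rois(m, max_rois = 10)
    orc <- oracle_roi_params(m$values, m$pixel_spacing_mm)
    if (is.null(orc)) {
      expect_equal(nrow(rois), 0)
      next
    }
    orc <- orc[order(-orc$area_mm2, -orc$prob_max, orc$centroid_row, orc$centroid_col), ]
    orc <- head(orc, 10)
    expect_equal(nrow(rois), nrow(orc))
    for (col in c("pixel_count", "area_mm2", "woap", "prob_mean", "prob_max")) {
      expect_equal(rois[[col]], orc[[col]], ignore_attr = TRUE)
    }
  }
})

test_that("WOAP is the probability-weighted area", {
  v <- matrix(0, 4, 4); v[1:2, 1:2] <- 0.5
  m <- probability_map(v, 1)
  expect_equal(compute_woap(which(v > 0), m), 2.0)

  v2 <- matrix(0, 3, 3); v2[2, 2] <- 1
  expect_equal(compute_woap(which(v2 > 0), probability_map(v2, 2)), 4.0)

  set.seed(9)
  v3 <- matrix(runif(100), 10, 10)
  px <- sample(100, 20)
  m3 <- probability_map(v3, 1.3)
  expect_equal(compute_woap(px, m3), sum(v3[px]) * 1.3^2)
  expect_error(compute_woap(integer(0), m3), "empty ROI")
})

test_that("ROI parameters are invariant under map rotation", {
  set.seed(13)
  m <- random_blob_map(32)
  rot <- probability_map(t(m$values)[ncol(m$values):1, ], m$pixel_spacing_mm)
  a <- extract_rois(m)
  b <- extract_rois(rot)
  for (col in c("pixel_count", "area_mm2", "woap", "prob_mean", "prob_median", "prob_max")) {
    expect_equal(sort(a[[col]]), sort(b[[col]]))
  }
})

test_that("returned pixel counts never exceed the mask and truncate at max_rois", {
  set.seed(29)
  for (i in 1:5) {
    m <- random_blob_map(32, n_blobs = 5)
    rois <- extract_rois(m, max_rois = 3)
    expect_lte(nrow(rois), 3)
    expect_lte(sum(rois$pixel_count), sum(m$values > 0.2))
    expect_true(all(diff(rois$area_mm2) <= 0))
  }
})

test_that("2x downsampling changes large-ROI areas by less than 10%", {
  cfg <- cohort_config(grid_size = c(128, 128), pixel_spacing_mm = 1, seed = 4)
  nod <- tibble::tibble(center_row = 64, center_col = 64,
                        peak_probability = 0.9, apparent_radius_mm = 12)
  m <- render_probability_map(nod, cfg)
  a1 <- extract_rois(m)$area_mm2
  expect_gte(extract_rois(m)$pixel_count[1], 100)
  down <- probability_map(m$values[seq(1, 128, 2), seq(1, 128, 2)], 2)
  a2 <- extract_rois(down)$area_mm2
  expect_lt(abs(a2 - a1) / a1, 0.10)
})

test_that("ROI-nodule matching is greedy nearest-centroid with a distance gate", {
  expect_equal(match_rois_to_nodules(
    tibble::tibble(centroid_row = numeric(), centroid_col = numeric()),
    tibble::tibble(nodule_id = character(), center_row = numeric(),
                   center_col = numeric(), apparent_radius_mm = numeric()), 1),
    character(0))

  rois <- tibble::tibble(centroid_row = 10, centroid_col = 10)
  truth <- tibble::tibble(nodule_id = "n1", center_row = 11, center_col = 10,
                          apparent_radius_mm = 5)
  expect_equal(match_rois_to_nodules(rois, truth, 1), "n1")

  # crossed 2x2 case: greedy must equal the brute-force minimum-total-distance
  # assignment (here unambiguous)
  rois2 <- tibble::tibble(centroid_row = c(10, 30), centroid_col = c(10, 10))
  truth2 <- tibble::tibble(nodule_id = c("a", "b"),
                           center_row = c(28, 12), center_col = c(10, 10),
                           apparent_radius_mm = c(20, 20))
  got <- match_rois_to_nodules(rois2, truth2, 1)
  d <- function(i, j) abs(rois2$centroid_row[i] - truth2$center_row[j])
  straight <- d(1, 1) + d(2, 2)
  crossed <- d(1, 2) + d(2, 1)
  best <- if (crossed < straight) c("b", "a") else c("a", "b")
  expect_equal(got, best)

  # beyond the gate: unmatched
  far <- tibble::tibble(nodule_id = "z", center_row = 500, center_col = 500,
                        apparent_radius_mm = 2)
  expect_true(is.na(match_rois_to_nodules(rois, far, 1)))
})

test_that("anisotropic pixel spacing is rejected", {
  expect_error(probability_map(matrix(0.5, 4, 4), c(0.5, 0.7)), "anisotropic")
  expect_silent(probability_map(matrix(0.5, 4, 4), c(0.7, 0.7)))
})
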