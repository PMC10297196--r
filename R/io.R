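# Readers and writers for probability maps (16-bit TIFF / PNG / text
# matrix), cohort tables (CSV) and run manifests (JSON).

#' Read a probability map from disk
#'
#' Accepts 16-bit or 8-bit grayscale TIFF or PNG (values scaled to \[0, 1\]
#' by the bit-depth maximum, which the underlying readers already perform),
#' or a whitespace-delimited plain-text matrix of probabilities. RGB images
#' are rejected.
#'
#' @param path Image or text-matrix file; format chosen by extension
#'   (`.tif`/`.tiff`, `.png`, anything else read as text).
#' @param pixel_spacing_mm Isotropic pixel spacing, mm/pixel.
#' @param image_id Identifier; defaults to the file name without extension.
#' @return A [probability_map()].
#' @export
read_probability_map <- function(path, pixel_spacing_mm,
                                 image_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  vals <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    as.matrix(utils::read.table(path))
  )
  if (length(dim(vals)) == 3) {
    if (dim(vals)[3] > 1 && !all(vals[, , 1] == vals[, , 2])) {
      stop("format error: ", basename(path), " is not a grayscale image", call. = FALSE)
    }
    vals <- vals[, , 1]
  }
  dimnames(vals) <- NULL
  probability_map(vals, pixel_spacing_mm, image_id = image_id)
}

#' Write a probability map as 16-bit grayscale TIFF
#'
#' Pixels are stored as `round(p * 65535)`; the 1/65535 quantization is far
#' below any modeled effect, and the round trip through
#' [read_probability_map()] is exact at that resolution.
#'
#' @param map A [probability_map()].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_probability_map <- function(map, path) {
  stopifnot(inherits(map, "camvol_probability_map"))
  tiff::writeTIFF(round(map$values * 65535) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write / read cohort and result tables as CSV
#'
#' Plain CSV with a header row via readr; identical input yields
#' byte-identical files, which the end-to-end determinism contract relies on.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `write_table_csv` returns `path` invisibly; `read_table_csv`
#'   returns a tibble.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
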