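#' Normalized Difference Vegetation Index
#'
#' `NDVI = (NIR - RED) / (NIR + RED)` per pixel, in [-1, 1]. For Landsat 7
#' ETM+ the bands are B4 (NIR) and B3 (RED); for Landsat 8 OLI, B5 and B4 —
#' which file is which is a property of the inputs, not of this function.
#' Pixels where both bands are zero (or either is missing) are undefined and
#' returned as `NA`.
#'
#' @param nir,red Numeric arrays (matrices or vectors) of surface
#'   reflectance in [0, 1], same shape.
#'
#' @return Array of NDVI values, same shape as the inputs.
#'
#' @examples
#' ndvi(0.6, 0.2)
#' ndvi(matrix(0.3, 2, 2), matrix(0.3, 2, 2))
#' @export
ndvi <- function(nir, red) {
  if (!identical(dim(nir), dim(red)) || length(nir) != length(red)) {
    rlang::abort("`nir` and `red` must have the same shape.",
                 class = "climwindow_invalid_argument")
  }
  if (any(nir < 0 | nir > 1, na.rm = TRUE) ||
      any(red < 0 | red > 1, na.rm = TRUE)) {
    rlang::warn("reflectance values outside [0, 1] detected.")
  }
  denom <- nir + red
  out <- (nir - red) / denom
  out[!is.na(denom) & denom == 0] <- NA_real_
  out
}

#' Percent vegetation cover from an NDVI array
#'
#' Classifies masked pixels with NDVI strictly greater than the threshold as
#' vegetation and returns their percentage among masked pixels with a
#' defined NDVI. The default threshold is 0.2; pixels exactly at the
#' threshold are not vegetation. Undefined pixels are excluded from both
#' numerator and denominator.
#'
#' @param ndvi_array Numeric array of NDVI values.
#' @param mask Logical array of the same shape marking wetland-interior
#'   pixels; `NULL` uses every pixel.
#' @param threshold Classification threshold (default 0.2, strict `>`).
#' @param year Optional year label carried into the result.
#'
#' @return A one-row tibble: `year`, `percent_cover` (in [0, 100]),
#'   `n_pixels` (defined masked pixels).
#'
#' @examples
#' vegetation_percent(c(0.5, 0.5, 0.0, 0.0))
#' @export
vegetation_percent <- function(ndvi_array, mask = NULL, threshold = 0.2,
                               year = NA_integer_) {
  if (is.null(mask)) mask <- rep(TRUE, length(ndvi_array))
  if (length(mask) != length(ndvi_array)) {
    rlang::abort("`mask` must match the NDVI array's shape.",
                 class = "climwindow_invalid_argument")
  }
  v <- ndvi_array[as.logical(mask)]
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    rlang::abort("no defined masked pixels.",
                 class = "climwindow_no_result")
  }
  tibble::tibble(
    year = year,
    percent_cover = 100 * sum(v > threshold) / length(v),
    n_pixels = length(v)
  )
}

#' Yearly vegetation-cover series from reflectance rasters
#'
#' Applies [ndvi()] and [vegetation_percent()] to a list of reflectance
#' rasters (as produced by [generate_raster()] or read from single-band
#' files) and returns the yearly cover table.
#'
#' @param rasters List of rasters, each a list with elements `nir`, `red`,
#'   `mask`, `year`.
#' @param threshold NDVI classification threshold (default 0.2).
#' @param index `"ndvi"` is the only implemented spectral index; requesting
#'   `"ndwi"` is rejected (no defining formula is configured).
#'
#' @return A tibble with columns `year`, `percent_cover`, `n_pixels`.
#' @export
vegetation_cover_series <- function(rasters, threshold = 0.2,
                                    index = "ndvi") {
  if (!identical(index, "ndvi")) {
    rlang::abort(sprintf("spectral index '%s' is not implemented; only 'ndvi' is.",
                         index),
                 class = "climwindow_invalid_argument")
  }
  purrr::map_dfr(rasters, function(r) {
    vegetation_percent(ndvi(r$nir, r$red), r$mask, threshold, year = r$year)
  })
}

#' Read a single-band reflectance raster from a TIFF file
#'
#' Thin wrapper over `tiff::readTIFF()` for single-band reflectance images
#' (values already scaled to [0, 1]).
#'
#' @param path Path to a TIFF file.
#' @return A numeric matrix.
#' @export
read_reflectance_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    rlang::abort("package 'tiff' is required to read TIFF rasters.")
  }
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
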