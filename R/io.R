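# File interfaces: 16-bit TIFF slice rasters (HU offset by +1024), 8-bit
# PNG label maps, YAML sidecar metadata, and PNG/TIFF slice readers with a
# declared HU mapping.  There is no DICOM reader here; DICOM slices should
# be converted to 16-bit TIFF (HU + 1024) upstream, and the rescale
# slope/intercept declared via `hu_slope`/`hu_intercept` when reading other
# rasters.

.label_png_levels <- c(0, 127, 255) / 255   # EXCLUDED, FAT, MUSCLE

#' Write a slice image as 16-bit TIFF
#'
#' Pixel values are stored as `HU + 1024`, clamped to `[0, 65535]`; masked
#' out pixels carry the air sentinel (-1000 HU, stored as 24).
#'
#' @param image a [slice_image()].
#' @param path output file path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_phantom_tiff <- function(image, path) {
  stopifnot(inherits(image, "slice_image"))
  v <- round(image$pixels + 1024)
  v[!image$mask] <- 24                      # -1000 HU sentinel
  v <- pmin(pmax(v, 0), 65535)
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit TIFF slice written by [write_phantom_tiff()]
#'
#' @param path file path.
#' @param mask optional logical matrix; by default pixels at the air
#'   sentinel (-1000 HU) are masked out.
#' @return A [slice_image()].
#' @export
read_phantom_tiff <- function(path, mask = NULL) {
  v <- tiff::readTIFF(path)
  hu <- round(v * 65535) - 1024
  if (is.null(mask)) mask <- hu != -1000
  slice_image(hu, mask)
}

#' Write and read label maps as 8-bit PNG
#'
#' Labels are stored as grey levels 0 (excluded), 127 (fat), 255 (muscle).
#'
#' @param labels a [label_map()].
#' @param path file path (`.png`).
#' @return `write_label_png()` returns `path` invisibly; `read_label_png()`
#'   returns a [label_map()].
#' @export
write_label_png <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  v <- matrix(.label_png_levels[labels$labels + 1L],
              nrow(labels$labels), ncol(labels$labels))
  png::writePNG(v, path)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  codes <- vapply(as.vector(v),
                  function(x) which.min(abs(.label_png_levels - x)) - 1L,
                  integer(1))
  label_map(matrix(codes, nrow(v), ncol(v)))
}

#' Write a phantom spec as a YAML sidecar
#'
#' Records the true mixture parameters, frame size, geometry and seed of a
#' generated phantom next to its raster files.
#'
#' @param spec a [phantom_spec()].
#' @param path file path (`.yaml`).
#' @return `write_phantom_spec()` returns `path` invisibly;
#'   `read_phantom_spec()` returns a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  t <- spec$theta_true
  yaml::write_yaml(list(
    theta_true = list(e_f = t$e_f, e_m = t$e_m, s_f = t$s_f, s_m = t$s_m,
                      z = t$z),
    size = spec$size, geometry = spec$geometry, seed = spec$seed), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  phantom_spec(with(y$theta_true, mixture_params(e_f, e_m, s_f, s_m, z)),
               size = y$size, geometry = y$geometry, seed = y$seed)
}

#' Read a slice raster with a declared HU mapping
#'
#' Reads an 8- or 16-bit PNG/TIFF raster and converts raw grey values to HU
#' via `hu = hu_slope * raw + hu_intercept` (the rescale convention of CT
#' rasters exported to plain image formats).  PNG values are rescaled from
#' `[0, 1]` to the raw 8- or 16-bit integer range before the mapping.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`).
#' @param hu_slope,hu_intercept the declared raw-to-HU affine mapping.
#' @param bits raw bit depth of PNG input (8 or 16).
#' @param mask optional logical matrix of body pixels; defaults to all.
#' @return A [slice_image()].
#' @export
read_slice_image <- function(path, hu_slope = 1, hu_intercept = 0,
                             bits = 8, mask = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("tif", "tiff")) {
    v <- tiff::readTIFF(path)
    round(v * 65535)
  } else if (ext == "png") {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    round(v * (2^bits - 1))
  } else {
    stop("unsupported raster format: ", ext, call. = FALSE)
  }
  slice_image(hu_slope * raw + hu_intercept, mask)
}
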