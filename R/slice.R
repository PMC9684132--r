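#' Label codes for quasi-segmentation maps
#'
#' Integer codes used in [label_map()] rasters: `LABEL_EXCLUDED` (0) for
#' pixels outside the body mask, `LABEL_FAT` (1) and `LABEL_MUSCLE` (2).
#'
#' @export
LABEL_EXCLUDED <- 0L

#' @rdname LABEL_EXCLUDED
#' @export
LABEL_FAT <- 1L

#' @rdname LABEL_EXCLUDED
#' @export
LABEL_MUSCLE <- 2L

#' CT slice image
#'
#' A 2-D raster of HU-valued pixels with a body mask.  Masked-out pixels
#' (air, couch, background) are excluded from histogram extraction and
#' segmentation; their pixel values are irrelevant (the phantom generator
#' stores the air sentinel -1000 HU there).
#'
#' @param pixels numeric matrix of HU values.
#' @param mask logical matrix of the same shape; `TRUE` marks body
#'   (fat-or-muscle) pixels.  Defaults to all pixels.
#' @param provenance optional [phantom_spec()] recording how a synthetic
#'   slice was generated.
#' @return An object of class `slice_image`.
#' @export
slice_image <- function(pixels, mask = NULL, provenance = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  if (!is.logical(mask) || !identical(dim(mask), dim(pixels))) {
    stop("`mask` must be a logical matrix of the same shape as `pixels`",
         call. = FALSE)
  }
  structure(list(pixels = pixels, mask = mask, provenance = provenance),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> %d x %d pixels, %d masked-in (%.1f%%)%s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$mask),
              100 * mean(x$mask),
              if (!is.null(x$provenance)) ", synthetic phantom" else ""))
  invisible(x)
}

#' Fat/muscle label map
#'
#' Per-pixel labels of a quasi-segmentation `W*(Y)` or of a phantom's ground
#' truth: `LABEL_FAT`, `LABEL_MUSCLE`, or `LABEL_EXCLUDED` exactly where the
#' slice mask is false.
#'
#' @param labels integer matrix over the label codes.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels) {
  if (!is.matrix(labels) || !is.numeric(labels)) {
    stop("`labels` must be an integer matrix", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  if (!all(labels %in% c(LABEL_EXCLUDED, LABEL_FAT, LABEL_MUSCLE))) {
    stop("labels must be one of LABEL_EXCLUDED, LABEL_FAT, LABEL_MUSCLE",
         call. = FALSE)
  }
  structure(list(labels = labels), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  l <- x$labels
  cat(sprintf("<label_map> %d x %d: %d fat, %d muscle, %d excluded\n",
              nrow(l), ncol(l), sum(l == LABEL_FAT), sum(l == LABEL_MUSCLE),
              sum(l == LABEL_EXCLUDED)))
  invisible(x)
}

#' Extract the grey-value histogram of a slice
#'
#' Bins the HU values of all masked-in pixels.  The total count equals the
#' number of masked-in pixels \eqn{Q}.
#'
#' @param image a [slice_image()].
#' @param binning a [grey_binning()].
#' @return A [grey_histogram()].
#' @examples
#' img <- slice_image(matrix(c(-80, -80, 50, 50), 2, 2))
#' compute_histogram(img, grey_binning())
#' @export
compute_histogram <- function(image, binning) {
  stopifnot(inherits(image, "slice_image"))
  g <- image$pixels[image$mask]
  if (length(g) == 0L) {
    stop("slice has no masked-in pixels", call. = FALSE)
  }
  counts <- tabulate(bin_index(g, binning), nbins = binning$n_bins)
  grey_histogram(counts, binning)
}
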