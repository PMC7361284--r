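#' Construct a 2D image with physical pixel size
#'
#' The basic substrate of the cluster metric: a matrix of non-negative
#' intensities together with its physical pixel size in nanometres.
#' Rows are image y (top row first), columns are image x; all physical
#' coordinates used by the package are in nanometres with the origin at the
#' top-left image corner.
#'
#' @param pixels Numeric matrix of intensities, at least 8 x 8, finite.
#' @param pixel_size_nm Physical edge length of one pixel in nanometres
#'   (must be positive; super-resolution STED data are typically recorded
#'   at 15-25 nm/px).
#' @param allow_negative Permit negative values (used internally for filter
#'   responses before clamping). Raw images must be non-negative.
#' @return An object of class `image2d`.
#' @export
#' @examples
#' img <- image2d(matrix(0, 16, 16), pixel_size_nm = 20)
#' dim(img)
image2d <- function(pixels, pixel_size_nm, allow_negative = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_bad_arg("'pixels' must be a numeric matrix")
  if (any(dim(pixels) < 8L))
    stop_bad_arg("image must be at least 8 x 8 pixels, got ",
                 nrow(pixels), " x ", ncol(pixels))
  if (!all(is.finite(pixels)))
    stop_bad_arg("image contains non-finite pixel values")
  if (!allow_negative && any(pixels < 0))
    stop_bad_arg("raw image intensities must be non-negative")
  if (!is_scalar_num(pixel_size_nm) || pixel_size_nm <= 0)
    stop_bad_arg("'pixel_size_nm' must be a positive scalar")
  structure(pixels, pixel_size_nm = as.numeric(pixel_size_nm),
            class = c("image2d", "matrix", "array"))
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, %.3g nm/px, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_nm"),
              min(x), max(x)))
  invisible(x)
}

#' @rdname image2d
#' @param x Object to query.
#' @export
pixel_size_nm <- function(x) attr(x, "pixel_size_nm")

as_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "pixel_size_nm") <- NULL
  m
}

#' Write an image as a float TIFF with a JSON metadata sidecar
#'
#' Pixels are stored as a single-page 32-bit float TIFF. Because float TIFF
#' storage is defined on \[0, 1\], intensities are divided by a scale factor
#' (the image maximum, or 1 for an all-zero image) that is recorded in the
#' sidecar and reapplied on read. The sidecar (`<path>.json`) carries
#' `pixel_size_nm` and `intensity_scale`.
#'
#' @param img An [image2d()].
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image2d"))
  m <- as_matrix(img)
  scale <- max(m, 1e-300)
  if (scale <= 0) scale <- 1
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size_nm = pixel_size_nm(img), intensity_scale = scale),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a single-plane grayscale TIFF as an image2d
#'
#' The physical pixel size is resolved with a documented precedence:
#' a JSON sidecar (`<path>.json`, key `pixel_size_nm`) wins over TIFF
#' resolution tags, which win over the `pixel_size_nm` argument. If none of
#' the three is available the read fails: a cluster metric computed with a
#' wrong pixel size is silently wrong, so the pixel size is never guessed.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm Optional fallback pixel size in nanometres, used
#'   only when neither sidecar nor TIFF tags provide one.
#' @return An [image2d()].
#' @export
read_image <- function(path, pixel_size_nm = NULL) {
  if (!file.exists(path)) stop_bad_arg("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (length(pages) != 1L)
    stop_bad_arg("multi-page TIFF not supported (", length(pages),
                 " pages): ", path)
  m <- pages[[1L]]
  if (length(dim(m)) == 3L) {
    if (dim(m)[3L] == 1L) m <- m[, , 1L]
    else stop_bad_arg("multi-channel TIFF not supported (",
                      dim(m)[3L], " channels): ", path)
  }
  info <- attributes(pages[[1L]])
  scale <- 1
  px <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    px <- meta$pixel_size_nm
    scale <- meta$intensity_scale %||% 1
  }
  if (is.null(px) && !is.null(info$x.resolution) && info$x.resolution > 0) {
    # resolution tags store pixels per unit; unit "cm" assumed when absent
    unit_nm <- switch(info$resolution.unit %||% "cm",
                      inch = 2.54e7, cm = 1e7, 1e7)
    px <- unit_nm / info$x.resolution
  }
  if (is.null(px)) px <- pixel_size_nm
  if (is.null(px))
    stop_bad_arg("no pixel size available for ", path,
                 " (no sidecar, no TIFF resolution tags, no explicit value)")
  image2d(matrix(as.numeric(m) * scale, nrow(m), ncol(m)),
          pixel_size_nm = px)
}
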