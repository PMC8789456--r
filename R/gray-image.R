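#' Grayscale image container
#'
#' A `gray_image` is an integer matrix of pixel intensities on the discrete
#' range `0..levels - 1` (default 256 levels, i.e. 8-bit). Rows index image
#' height, columns width. Most functions in the package accept a plain
#' matrix and coerce it with [as_gray_image()].
#'
#' @param pixels numeric or integer matrix of intensities.
#' @param levels number of gray levels `L`; pixel values must lie in
#'   `[0, L - 1]`.
#' @return An integer matrix with class `gray_image` and attribute `levels`.
#' @examples
#' img <- gray_image(matrix(0:3, 2, 2), levels = 256)
#' gray_levels(img)
#' @export
gray_image <- function(pixels, levels = 256L) {
  if (!is.matrix(pixels)) {
    stop("`pixels` must be a matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have positive height and width", call. = FALSE)
  }
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) {
    stop("`levels` must be an integer >= 2", call. = FALSE)
  }
  px <- pixels
  storage.mode(px) <- "integer"
  if (anyNA(px)) stop("pixel intensities must be finite", call. = FALSE)
  if (any(px < 0L) || any(px > levels - 1L)) {
    stop("pixel intensities must lie in [0, levels - 1]", call. = FALSE)
  }
  structure(px, levels = levels, class = c("gray_image", class(px)))
}

#' @rdname gray_image
#' @param x object to coerce or query.
#' @export
as_gray_image <- function(x, levels = 256L) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(as.matrix(x), levels = levels)
}

#' @rdname gray_image
#' @export
gray_levels <- function(x) {
  lv <- attr(x, "levels")
  if (is.null(lv)) 256L else as.integer(lv)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, %d levels, intensity range [%d, %d]\n",
    nrow(x), ncol(x), gray_levels(x), min(x), max(x)
  ))
  invisible(x)
}

#' Read and write grayscale PNG images
#'
#' `read_gray_png()` reads a PNG as an 8-bit grayscale [gray_image()]; color
#' images are converted by the Rec. 601 luminance (0.299 R + 0.587 G +
#' 0.114 B). `write_gray_png()` writes a `gray_image` (or 0/1 logical mask)
#' as an 8-bit grayscale PNG.
#'
#' @param path file path.
#' @return `read_gray_png()` returns a [gray_image()].
#' @export
read_gray_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    arr <- if (nc >= 3L) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  }
  gray_image(round(arr * 255), levels = 256L)
}

#' @rdname read_gray_png
#' @param image a [gray_image()], numeric matrix, or logical mask.
#' @export
write_gray_png <- function(image, path) {
  if (is.logical(image)) {
    m <- matrix(as.numeric(image), nrow(image), ncol(image))
  } else {
    m <- unclass(image) / (gray_levels(image) - 1L)
    m <- matrix(as.numeric(m), nrow(image), ncol(image))
  }
  png::writePNG(m, path)
  invisible(path)
}

#' Slice a NIfTI volume into windowed grayscale images
#'
#' Optional loader for NIfTI CT volumes (requires the RNifti package).
#' Each axial slice is linearly windowed: intensities in
#' `[center - width/2, center + width/2]` map to `[0, 255]` and are clamped
#' outside the window.
#'
#' @param path NIfTI file path.
#' @param center,width window center and width in the volume's intensity
#'   units (for CT, Hounsfield units; default brain window 40/80).
#' @return A list of [gray_image()] slices.
#' @export
read_nifti_slices <- function(path, center = 40, width = 80) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI volumes requires the RNifti package", call. = FALSE)
  }
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  if (length(d) < 2L) stop("volume must be at least 2-D", call. = FALSE)
  nsl <- if (length(d) == 2L) 1L else d[3]
  lo <- center - width / 2
  lapply(seq_len(nsl), function(k) {
    sl <- if (length(d) == 2L) vol[, ] else vol[, , k]
    sc <- pmin(pmax((sl - lo) / width, 0), 1)
    gray_image(round(sc * 255), levels = 256L)
  })
}

#' Peak signal-to-noise ratio between two images
#'
#' @param image,reference images (or matrices) of identical shape.
#' @param peak peak intensity; defaults to `levels - 1` of `reference`.
#' @return PSNR in decibels (`Inf` for identical images).
#' @export
psnr <- function(image, reference, peak = NULL) {
  a <- as.numeric(unclass(image))
  b <- as.numeric(unclass(reference))
  stopifnot(length(a) == length(b))
  if (is.null(peak)) peak <- gray_levels(reference) - 1L
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}
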