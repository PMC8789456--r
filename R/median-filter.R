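#' Median filtering of grayscale images
#'
#' Two exact implementations of the windowed median filter used to suppress
#' impulse (salt-and-pepper) noise on CT slices:
#'
#' * `median_filter_naive()` sorts each window and takes the lower median
#'   (for an odd window the lower median is the unique median). It serves as
#'   the reference implementation.
#' * `median_filter_bisection()` never materialises a per-window sort.
#'   For every pixel it keeps a candidate intensity range `[lo, hi]` and
#'   repeatedly halves it, keeping the half that holds at least half of the
#'   window's pixels (ties go to the lower half, matching the lower-median
#'   convention), until the range collapses to one bin. The result is
#'   bit-identical to the naive filter on every input.
#'
#' Both run vectorised over all pixels at once.
#'
#' @param image a [gray_image()] or numeric matrix.
#' @param window odd window side length (default 3).
#' @param border how the image border is padded: `"reflect"` (edge-inclusive
#'   mirror, default), `"edge"` (replicate border pixel), or `"zero"`.
#' @return A [gray_image()] of the same shape. Output intensities are a
#'   subset of input intensities (a median never invents a value).
#' @examples
#' img <- gray_image(matrix(c(0, 0, 0, 0, 255, 0, 0, 0, 0), 3, 3))
#' median_filter_naive(img, window = 3)
#' @export
median_filter_naive <- function(image, window = 3L, border = c("reflect", "edge", "zero")) {
  border <- match.arg(border)
  image <- as_gray_image(image)
  stack <- window_stack(image, window, border)
  n <- dim(stack)[3]
  rank <- (n + 1L) %/% 2L # lower median
  out <- apply(stack, c(1L, 2L), function(v) sort.int(v, method = "quick")[rank])
  gray_image(out, levels = gray_levels(image))
}

#' @rdname median_filter_naive
#' @export
median_filter_bisection <- function(image, window = 3L, border = c("reflect", "edge", "zero")) {
  border <- match.arg(border)
  image <- as_gray_image(image)
  stack <- window_stack(image, window, border)
  n <- dim(stack)[3]
  h <- nrow(image)
  w <- ncol(image)
  lo <- matrix(0L, h, w)
  hi <- matrix(gray_levels(image) - 1L, h, w)
  while (any(lo < hi)) {
    mid <- (lo + hi) %/% 2L
    cnt <- matrix(0L, h, w)
    for (k in seq_len(n)) cnt <- cnt + (stack[, , k] <= mid)
    lower <- 2L * cnt >= n # tie -> keep lower half (lower-median convention)
    hi[lower] <- mid[lower]
    lo[!lower] <- mid[!lower] + 1L
  }
  gray_image(lo, levels = gray_levels(image))
}

# Stack of shifted padded copies: result[i, j, k] is the k-th window value
# of pixel (i, j). Shared by both filters; the filters differ only in how
# they reduce the third dimension to a median.
window_stack <- function(image, window, border) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  }
  h <- nrow(image)
  w <- ncol(image)
  if (window > min(h, w)) {
    stop("`window` must not exceed the image's smaller dimension", call. = FALSE)
  }
  p <- (window - 1L) %/% 2L
  padded <- pad_matrix(unclass(image), p, border)
  stack <- array(0L, dim = c(h, w, window * window))
  k <- 0L
  for (di in 0:(window - 1L)) {
    for (dj in 0:(window - 1L)) {
      k <- k + 1L
      stack[, , k] <- padded[di + seq_len(h), dj + seq_len(w)]
    }
  }
  stack
}

pad_matrix <- function(m, p, border) {
  if (p == 0L) return(m)
  h <- nrow(m)
  w <- ncol(m)
  ridx <- switch(border,
    reflect = c(p:1, seq_len(h), h:(h - p + 1L)),
    edge = c(rep(1L, p), seq_len(h), rep(h, p)),
    zero = c(seq_len(h)) # handled below
  )
  cidx <- switch(border,
    reflect = c(p:1, seq_len(w), w:(w - p + 1L)),
    edge = c(rep(1L, p), seq_len(w), rep(w, p)),
    zero = c(seq_len(w))
  )
  if (border == "zero") {
    out <- matrix(0L, h + 2L * p, w + 2L * p)
    out[p + seq_len(h), p + seq_len(w)] <- m
    return(out)
  }
  m[ridx, cidx, drop = FALSE]
}
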