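#' Inverted-bottleneck encoder configuration
#'
#' An EfficientNet-style feature extractor built from inverted-bottleneck
#' (MBConv) blocks: a pointwise expansion, a depthwise 3x3 convolution
#' (same padding), and a linear pointwise compression, with a residual
#' connection whenever stride is 1 and channel counts match. A strided stem
#' convolution precedes the blocks; global average pooling and a seeded
#' linear head produce the output vector (default `m = 1000`, matching a
#' 1000-unit classification head).
#'
#' @param stem_filters,stem_kernel,stem_stride stem convolution spec.
#' @param blocks list of block specs, each a list with `out_channels`,
#'   `expansion`, `stride`, and `kernel`.
#' @param output_dim head width `m`.
#' @param seed integer seed for the deterministic weight draw.
#' @return A config list for [bottleneck_encode()].
#' @export
bottleneck_config <- function(stem_filters = 8L, stem_kernel = 3L, stem_stride = 2L,
                              blocks = list(
                                list(out_channels = 16L, expansion = 4L, stride = 2L, kernel = 3L),
                                list(out_channels = 24L, expansion = 4L, stride = 2L, kernel = 3L),
                                list(out_channels = 24L, expansion = 4L, stride = 1L, kernel = 3L)
                              ),
                              output_dim = 1000L, seed = 42L) {
  if (output_dim < 1L) stop("`output_dim` must be >= 1", call. = FALSE)
  for (b in blocks) {
    if (b$expansion < 1L) stop("block expansion factor must be >= 1", call. = FALSE)
  }
  list(
    stem_filters = as.integer(stem_filters), stem_kernel = as.integer(stem_kernel),
    stem_stride = as.integer(stem_stride), blocks = blocks,
    output_dim = as.integer(output_dim), seed = as.integer(seed)
  )
}

bottleneck_block_weights <- function(in_channels, spec, fan_scale = 1) {
  mid <- in_channels * spec$expansion
  list(
    expand = draw_weights(c(in_channels, mid), fan_in = in_channels),
    depthwise = draw_weights(c(spec$kernel, spec$kernel, mid), fan_in = spec$kernel^2),
    compress = draw_weights(c(mid, spec$out_channels), fan_in = mid)
  )
}

#' One inverted-bottleneck block
#'
#' Pointwise expand (SiLU) -> depthwise convolution (SiLU, same padding,
#' optional stride) -> linear pointwise compression; the input is added
#' back when `stride == 1` and the channel counts match.
#'
#' @param x input activation array `H x W x C`.
#' @param weights list with `expand` (`C x C*e`), `depthwise`
#'   (`k x k x C*e`), and `compress` (`C*e x C_out`) arrays, e.g. from the
#'   seeded initializer used by [bottleneck_encode()].
#' @param stride depthwise stride.
#' @return The output activation array.
#' @export
bottleneck_block <- function(x, weights, stride = 1L) {
  a <- silu(pointwise_conv2d(x, weights$expand))
  a <- silu(depthwise_conv2d(a, weights$depthwise, stride = stride, padding = "same"))
  out <- pointwise_conv2d(a, weights$compress)
  if (stride == 1L && dim(out)[3] == dim(x)[3]) out <- out + x
  out
}

bottleneck_weights <- function(cfg) {
  with_opt_seed(cfg$seed, {
    w <- list(
      stem = draw_weights(c(cfg$stem_kernel, cfg$stem_kernel, 1L, cfg$stem_filters),
                          fan_in = cfg$stem_kernel^2)
    )
    cin <- cfg$stem_filters
    w$blocks <- lapply(cfg$blocks, function(spec) {
      bw <- bottleneck_block_weights(cin, spec)
      cin <<- spec$out_channels
      bw
    })
    w$head <- draw_weights(c(cin, cfg$output_dim), fan_in = cin)
    w
  })
}

#' Encode an image with the inverted-bottleneck network
#'
#' @param image a [gray_image()] or numeric matrix; intensities are scaled
#'   to `[0, 1]`.
#' @param cfg a [bottleneck_config()].
#' @return A numeric feature vector of length `cfg$output_dim` with
#'   attribute `source = "bottleneck"`. Deterministic given the config
#'   seed; all-zero input yields a finite output (there are no
#'   normalization layers to divide by zero).
#' @export
bottleneck_encode <- function(image, cfg = bottleneck_config()) {
  img <- as_gray_image(image)
  x <- unclass(img) / (gray_levels(img) - 1)
  w <- bottleneck_weights(cfg)
  a <- silu(conv2d(array(x, dim = c(dim(x), 1L)), w$stem, stride = cfg$stem_stride))
  for (i in seq_along(cfg$blocks)) {
    a <- bottleneck_block(a, w$blocks[[i]], stride = cfg$blocks[[i]]$stride)
  }
  pooled <- apply(a, 3L, mean) # global average pool
  out <- as.numeric(pooled %*% w$head)
  structure(out, source = "bottleneck")
}
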