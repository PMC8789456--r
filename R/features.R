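#' Fuse two feature vectors by concatenation
#'
#' The capsule-path and bottleneck-path features are combined into a single
#' vector of length `q = n + m` (1186 under the reference configurations:
#' 186 capsule features + 1000 bottleneck features). Values are preserved
#' verbatim; `split_fused()` recovers both inputs exactly.
#'
#' @param a,b numeric feature vectors (capsule path first by convention).
#' @return A numeric vector of class `fused_features` with attribute
#'   `split = c(n, m)`.
#' @examples
#' f <- fuse_features(1:3, 4:5)
#' length(f)
#' split_fused(f)
#' @export
fuse_features <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b)))) {
    stop("feature vectors must be finite", call. = FALSE)
  }
  structure(c(a, b), split = c(length(a), length(b)), class = "fused_features")
}

#' @rdname fuse_features
#' @param f a `fused_features` vector.
#' @export
split_fused <- function(f) {
  s <- attr(f, "split")
  if (is.null(s)) stop("`f` has no recorded split", call. = FALSE)
  v <- as.numeric(f)
  list(a = v[seq_len(s[1])], b = v[s[1] + seq_len(s[2])])
}

#' Shannon entropy of each feature column
#'
#' Each column is discretized into `bins` equal-width bins over its
#' observed range and scored by the Shannon entropy `-sum p log2 p` of the
#' bin occupancies. A constant column has a single occupied bin and scores
#' exactly 0.
#'
#' @param x numeric matrix or data frame, samples in rows.
#' @param bins number of equal-width bins (>= 2, default 16).
#' @return Numeric vector of per-column entropies in bits.
#' @export
feature_entropy <- function(x, bins = 16L) {
  x <- as.matrix(x)
  bins <- as.integer(bins)
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  apply(x, 2L, function(col) {
    rng <- range(col)
    if (rng[1] == rng[2]) return(0)
    idx <- pmin(bins, floor((col - rng[1]) / (rng[2] - rng[1]) * bins) + 1L)
    p <- tabulate(idx, nbins = bins)
    p <- p[p > 0] / length(col)
    -sum(p * log2(p))
  })
}

#' Entropy-based feature selection
#'
#' Ranks feature columns by [feature_entropy()] and keeps the `keep`
#' highest-scoring ones. Ties are broken in favour of the lower column
#' index. Permuting columns permutes the selection accordingly.
#'
#' @inheritParams feature_entropy
#' @param keep number of columns to keep (`<= ncol(x)`).
#' @return Integer vector of the selected column indices, in rank order.
#' @export
entropy_select <- function(x, keep, bins = 16L) {
  x <- as.matrix(x)
  keep <- as.integer(keep)
  if (keep > ncol(x)) {
    stop("`keep` must not exceed the number of feature columns", call. = FALSE)
  }
  if (keep < 1L) stop("`keep` must be >= 1", call. = FALSE)
  H <- feature_entropy(x, bins = bins)
  order(-H, seq_along(H))[seq_len(keep)]
}

#' Extract fused features for a set of images
#'
#' Runs both encoders on every image and stacks the fused vectors into a
#' samples-by-features matrix.
#'
#' @param images list of [gray_image()] objects (or matrices).
#' @param caps_cfg,bottleneck_cfg encoder configurations.
#' @param progress print a dot every 25 images.
#' @return Numeric matrix, one row per image, `n + m` columns.
#' @export
extract_fused_features <- function(images, caps_cfg = caps_config(),
                                   bottleneck_cfg = bottleneck_config(),
                                   progress = FALSE) {
  rows <- lapply(seq_along(images), function(i) {
    if (progress && i %% 25L == 0L) cat(".")
    as.numeric(fuse_features(
      capsnet_encode(images[[i]], caps_cfg),
      bottleneck_encode(images[[i]], bottleneck_cfg)
    ))
  })
  if (progress) cat("\n")
  do.call(rbind, rows)
}
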