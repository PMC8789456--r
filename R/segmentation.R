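#' Intensity histogram of a grayscale image
#'
#' @param image a [gray_image()] or integer matrix.
#' @param levels gray-level count when `image` is a plain matrix.
#' @return A tibble of class `intensity_histogram` with columns `level`
#'   (0..L-1), `count`, and `p` (relative frequency, summing to 1), plus
#'   attributes `levels` and `n_pixels`.
#' @export
img_histogram <- function(image, levels = NULL) {
  image <- as_gray_image(image, levels = levels %||% 256L)
  L <- gray_levels(image)
  counts <- tabulate(as.integer(image) + 1L, nbins = L)
  n <- length(image)
  out <- tibble::tibble(level = 0:(L - 1L), count = counts, p = counts / n)
  structure(out, levels = L, n_pixels = n,
            class = c("intensity_histogram", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accept an intensity_histogram, a probability vector, or a count vector.
hist_probs <- function(hist) {
  if (inherits(hist, "intensity_histogram")) {
    p <- hist$p
  } else if (is.numeric(hist)) {
    s <- sum(hist)
    if (s <= 0) stop("histogram has no mass", call. = FALSE)
    p <- hist / s
  } else {
    stop("`hist` must be an intensity_histogram or a numeric vector", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-12) p <- p / sum(p)
  p
}

check_thresholds <- function(thresholds, L) {
  t <- as.integer(round(thresholds))
  if (length(t) < 1L) stop("need at least one threshold", call. = FALSE)
  if (any(diff(t) <= 0L)) stop("thresholds must be strictly increasing", call. = FALSE)
  if (any(t < 0L) || any(t > L - 2L)) {
    stop("thresholds must lie in [0, L - 2]", call. = FALSE)
  }
  t
}

#' Per-segment mass and mean under a threshold set
#'
#' Thresholds `t_1 < ... < t_k` split the level range into `k + 1` segments
#' with segment `n` covering levels `(t_(n-1), t_n]` (taking `t_0 = -1` and
#' `t_(k+1) = L - 1`).
#'
#' @param hist an [img_histogram()] result or probability vector.
#' @param thresholds strictly increasing integer thresholds in `[0, L-2]`.
#' @return A tibble with columns `segment`, `omega` (mass), `mu` (mean
#'   intensity; 0 for an empty segment), and `degenerate` (zero-mass flag).
#' @export
class_stats <- function(hist, thresholds) {
  p <- hist_probs(hist)
  L <- length(p)
  t <- check_thresholds(thresholds, L)
  edges <- c(-1L, t, L - 1L)
  k1 <- length(edges) - 1L
  omega <- numeric(k1)
  mu <- numeric(k1)
  lev <- 0:(L - 1L)
  for (n in seq_len(k1)) {
    idx <- which(lev > edges[n] & lev <= edges[n + 1L])
    omega[n] <- sum(p[idx])
    mu[n] <- if (omega[n] > 0) sum(lev[idx] * p[idx]) / omega[n] else 0
  }
  tibble::tibble(
    segment = seq_len(k1) - 1L, omega = omega, mu = mu,
    degenerate = omega == 0
  )
}

#' Between-class variance of a multilevel threshold set
#'
#' The multilevel Otsu criterion: the pairwise sum
#' `d(t) = sum_(n<m) omega_n * omega_m * (mu_n - mu_m)^2` over the `k + 1`
#' segments induced by the thresholds. Empty segments contribute zero. For
#' `k = 1` this reduces to `omega_0 * omega_1 * (mu_0 - mu_1)^2`, and when
#' the masses sum to one it equals the classical between-class variance
#' `sum_n omega_n * (mu_n - mu)^2`.
#'
#' @inheritParams class_stats
#' @return The scalar criterion value.
#' @export
between_class_variance <- function(hist, thresholds) {
  st <- class_stats(hist, thresholds)
  k1 <- nrow(st)
  d <- 0
  for (n in seq_len(k1 - 1L)) {
    for (m in (n + 1L):k1) {
      if (st$omega[n] > 0 && st$omega[m] > 0) {
        d <- d + st$omega[n] * st$omega[m] * (st$mu[n] - st$mu[m])^2
      }
    }
  }
  d
}

# Fast evaluator used by the exhaustive search and the SOA objective:
# precomputes cumulative mass/moment so one threshold set costs O(k^2).
bcv_evaluator <- function(p) {
  L <- length(p)
  cp <- cumsum(p)                  # mass of levels 0..i
  cm <- cumsum((0:(L - 1L)) * p)   # first moment of levels 0..i
  function(t) {
    edges <- c(0L, t + 1L, L) # segment n covers levels edges[n]..edges[n+1]-1
    k1 <- length(edges) - 1L
    om <- numeric(k1)
    mu <- numeric(k1)
    for (n in seq_len(k1)) {
      lo <- edges[n]
      hi <- edges[n + 1L]
      mass <- cp[hi] - if (lo > 0L) cp[lo] else 0
      mom <- cm[hi] - if (lo > 0L) cm[lo] else 0
      om[n] <- mass
      mu[n] <- if (mass > 0) mom / mass else 0
    }
    d <- 0
    for (n in seq_len(k1 - 1L)) {
      for (m in (n + 1L):k1) {
        if (om[n] > 0 && om[m] > 0) d <- d + om[n] * om[m] * (mu[n] - mu[m])^2
      }
    }
    d
  }
}

#' Exhaustive multilevel Otsu thresholding
#'
#' Global argmax of [between_class_variance()] by full enumeration of all
#' threshold tuples `0 < t_1 < ... < t_k <= L - 2`. Supported for
#' `k in {1, 2, 3}` (the combinatorial budget); ties are broken by the
#' lexicographically smallest tuple.
#'
#' @inheritParams class_stats
#' @param k number of thresholds.
#' @return A list with `thresholds` (integer vector) and `score`.
#' @export
otsu_exhaustive <- function(hist, k = 1L) {
  p <- hist_probs(hist)
  L <- length(p)
  k <- as.integer(k)
  if (k < 1L || k > 3L) {
    stop("`k` must be 1, 2, or 3 for the exhaustive search", call. = FALSE)
  }
  if (k >= L - 1L) stop("`k` must be smaller than the level count minus 1", call. = FALSE)
  ev <- bcv_evaluator(p)
  best <- -Inf
  best_t <- NULL
  cand <- 1:(L - 2L)
  if (k == 1L) {
    for (t1 in cand) {
      s <- ev(t1)
      if (s > best) {
        best <- s
        best_t <- t1
      }
    }
  } else if (k == 2L) {
    for (t1 in cand[-length(cand)]) {
      for (t2 in (t1 + 1L):(L - 2L)) {
        s <- ev(c(t1, t2))
        if (s > best) {
          best <- s
          best_t <- c(t1, t2)
        }
      }
    }
  } else {
    for (t1 in 1:(L - 4L)) {
      for (t2 in (t1 + 1L):(L - 3L)) {
        for (t3 in (t2 + 1L):(L - 2L)) {
          s <- ev(c(t1, t2, t3))
          if (s > best) {
            best <- s
            best_t <- c(t1, t2, t3)
          }
        }
      }
    }
  }
  list(thresholds = as.integer(best_t), score = best)
}

#' SOA-driven multilevel Otsu thresholding
#'
#' Maximizes [between_class_variance()] with the seagull optimization
#' algorithm over `k` continuous coordinates in `[1, L - 2]`. Each
#' candidate position is sorted and rounded to integers before evaluation;
#' candidates whose rounded thresholds collide get `-Inf` fitness
#' (rejected rather than repaired).
#'
#' @param image a [gray_image()] or matrix (its histogram is the input).
#' @param k number of thresholds (default 2: background / brain tissue /
#'   hyperdense lesion).
#' @param params SOA parameters from [soa_params()].
#' @return A list of class `otsu_result`: `thresholds`, `score` (the
#'   between-class variance of the returned set), and `optimizer` (the full
#'   `swarm_opt` run).
#' @export
otsu_soa <- function(image, k = 2L, params = soa_params()) {
  h <- img_histogram(image)
  L <- attr(h, "levels")
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (k >= L - 1L) stop("`k` must be smaller than the level count minus 1", call. = FALSE)
  ev <- bcv_evaluator(h$p)
  obj <- function(x) {
    t <- sort(as.integer(round(x)))
    if (anyDuplicated(t)) return(-Inf)
    ev(t)
  }
  res <- soa_optimize(obj, lower = rep(1, k), upper = rep(L - 2, k),
                      params = params, sense = "maximize")
  t <- sort(as.integer(round(res$best_position)))
  structure(
    list(thresholds = t, score = ev(t), optimizer = res),
    class = "otsu_result"
  )
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf(
    "<otsu_result> thresholds: %s (between-class variance %.6g)\n",
    paste(x$thresholds, collapse = ", "), x$score
  ))
  invisible(x)
}

#' Apply a threshold set to an image
#'
#' Pixel with intensity `v` receives label `n` when `t_n < v <= t_(n+1)`
#' (with `t_0 = -1`, `t_(k+1) = L - 1`), giving `k + 1` labels `0..k`.
#'
#' @param image a [gray_image()] or matrix.
#' @param thresholds strictly increasing integer thresholds.
#' @return An integer label matrix with attribute `n_labels`.
#' @export
apply_thresholds <- function(image, thresholds) {
  image <- as_gray_image(image)
  L <- gray_levels(image)
  t <- check_thresholds(thresholds, L)
  lab <- matrix(0L, nrow(image), ncol(image))
  for (tt in t) lab <- lab + (unclass(image) > tt)
  structure(lab, n_labels = length(t) + 1L)
}

#' Extract the lesion mask from a label image
#'
#' Acute haemorrhage is hyperdense on CT, so by default the mask is the
#' highest-intensity segment.
#'
#' @param labels an [apply_thresholds()] result.
#' @param label which label to extract; default the highest.
#' @return A logical matrix.
#' @export
lesion_mask <- function(labels, label = NULL) {
  n <- attr(labels, "n_labels") %||% (max(labels) + 1L)
  if (is.null(label)) label <- n - 1L
  unclass(labels) == label
}

#' Variance decomposition at a single threshold
#'
#' For one threshold the total intensity variance splits exactly into the
#' within-class and between-class parts:
#' `sigma2_total = sigma2_within + sigma2_between`.
#'
#' @inheritParams class_stats
#' @param threshold a single threshold.
#' @return A tibble with `total`, `within`, and `between` variances.
#' @export
variance_decomposition <- function(hist, threshold) {
  p <- hist_probs(hist)
  L <- length(p)
  lev <- 0:(L - 1L)
  mu <- sum(lev * p)
  total <- sum((lev - mu)^2 * p)
  st <- class_stats(p, threshold)
  within <- 0
  t <- check_thresholds(threshold, L)
  edges <- c(-1L, t, L - 1L)
  for (n in seq_len(nrow(st))) {
    idx <- which(lev > edges[n] & lev <= edges[n + 1L])
    if (st$omega[n] > 0) {
      within <- within + sum((lev[idx] - st$mu[n])^2 * p[idx])
    }
  }
  tibble::tibble(
    total = total, within = within,
    between = between_class_variance(p, threshold)
  )
}
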