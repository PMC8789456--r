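# Shared fixtures, all generated in code under fixed seeds.

random_image <- function(seed, n = 16L, levels = 256L) {
  set.seed(seed)
  gray_image(matrix(sample(0:(levels - 1L), n * n, replace = TRUE), n, n),
             levels = levels)
}

# Two Gaussian intensity modes at 18 and 45 on 64 gray levels.
bimodal_image <- function(seed, n = 48L) {
  set.seed(seed)
  v <- c(round(rnorm(n * n / 2, 18, 4)), round(rnorm(n * n / 2, 45, 4)))
  v <- pmin(pmax(v, 0), 63)
  gray_image(matrix(v, n, n), levels = 64L)
}

trimodal_image <- function(seed, n = 48L) {
  set.seed(seed)
  v <- c(round(rnorm(ceiling(n * n / 3), 10, 3)),
         round(rnorm(ceiling(n * n / 3), 32, 3)),
         round(rnorm(ceiling(n * n / 3), 54, 3)))
  v <- pmin(pmax(v[seq_len(n * n)], 0), 63)
  gray_image(matrix(v, n, n), levels = 64L)
}

# Brute-force median by explicit per-window sorting with edge-inclusive
# reflect padding; written independently of the package implementation.
brute_median <- function(img, window = 3L) {
  m <- unclass(img)
  h <- nrow(m); w <- ncol(m)
  p <- (window - 1L) %/% 2L
  ridx <- c(p:1, 1:h, h:(h - p + 1L))
  cidx <- c(p:1, 1:w, w:(w - p + 1L))
  pad <- m[ridx, cidx]
  out <- matrix(0L, h, w)
  for (i in 1:h) for (j in 1:w) {
    v <- sort(as.vector(pad[i:(i + 2L * p), j:(j + 2L * p)]))
    out[i, j] <- v[(length(v) + 1L) %/% 2L]
  }
  out
}

# Two-class Gaussian fixture with a conditioning-friendly spread for
# dual-solver comparisons.
svm_fixture <- function(seed, n = 20L) {
  set.seed(seed)
  x <- matrix(rnorm(n * 2, sd = 1.5), n, 2)
  y <- rep(c(1, -1), each = n / 2)
  x[y == 1, ] <- x[y == 1, ] + 2
  list(x = x, y = y)
}
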