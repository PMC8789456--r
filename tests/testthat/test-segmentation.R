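test_that("histograms count and normalize correctly", {
  img <- gray_image(matrix(c(0L, 0L, 255L, 255L), 2, 2))
  h <- img_histogram(img)
  expect_equal(h$p[h$level == 0], 0.5)
  expect_equal(h$p[h$level == 255], 0.5)
  expect_equal(sum(h$p), 1)

  const <- gray_image(matrix(42L, 3, 3))
  hc <- img_histogram(const)
  expect_equal(hc$p[hc$level == 42], 1)

  expect_equal(sum(img_histogram(random_image(3))$p), 1)
})

test_that("between-class variance matches the two-delta closed form", {
  p <- numeric(256)
  p[1] <- 0.5    # level 0
  p[101] <- 0.5  # level 100
  expect_equal(between_class_variance(p, 50), 0.5 * 0.5 * 100^2)
  # all mass in one segment: empty segments contribute zero
  expect_equal(between_class_variance(p, 200), 0)
})

test_that("pairwise criterion at k=2 matches an independent double loop", {
  p <- rep(1 / 64, 64)
  stats_of <- function(idx) {
    w <- sum(p[idx])
    list(w = w, u = if (w > 0) sum((idx - 1) * p[idx]) / w else 0)
  }
  brute <- function(t1, t2) {
    s0 <- stats_of(seq_len(t1 + 1))
    s1 <- stats_of((t1 + 2):(t2 + 1))
    s2 <- stats_of((t2 + 2):64)
    s0$w * s1$w * (s0$u - s1$u)^2 + s0$w * s2$w * (s0$u - s2$u)^2 +
      s1$w * s2$w * (s1$u - s2$u)^2
  }
  best <- -Inf
  best_t <- NULL
  for (t1 in 1:61) for (t2 in (t1 + 1):62) {
    v <- brute(t1, t2)
    expect_equal(between_class_variance(p, c(t1, t2)), v)
    if (v > best) {
      best <- v
      best_t <- c(t1, t2)
    }
  }
  ex <- otsu_exhaustive(p, 2)
  expect_equal(ex$thresholds, best_t)
  expect_equal(ex$score, best)
})

test_that("exhaustive Otsu centres the threshold of a symmetric bimodal mix", {
  # equal-mass Gaussians at 60 and 190; the modes must be wide enough that
  # the criterion varies measurably between them (narrow modes make the
  # whole inter-mode range a numerical plateau)
  lev <- 0:255
  p <- dnorm(lev, 60, 15) + dnorm(lev, 190, 15)
  p <- p / sum(p)
  ex <- otsu_exhaustive(p, 1)
  expect_gte(ex$thresholds, 115)
  expect_lte(ex$thresholds, 135)
})

test_that("degenerate histograms fall back to the lexicographically smallest set", {
  p <- numeric(256)
  p[100] <- 1
  ex <- otsu_exhaustive(p, 1)
  expect_equal(ex$score, 0)
  expect_equal(ex$thresholds, 1L) # smallest candidate (0 < t)
  ex2 <- otsu_exhaustive(p, 2)
  expect_equal(ex2$thresholds, c(1L, 2L))
})

test_that("k=2 exhaustive separates a three-delta histogram", {
  p <- numeric(256)
  p[c(21, 121, 221)] <- 1 / 3 # levels 20, 120, 220
  ex <- otsu_exhaustive(p, 2)
  expect_gte(ex$thresholds[1], 20)
  expect_lt(ex$thresholds[1], 120)
  expect_gte(ex$thresholds[2], 120)
  expect_lt(ex$thresholds[2], 220)
})

test_that("unsupported k is rejected", {
  expect_error(otsu_exhaustive(rep(1 / 8, 8), 4), "k")
  expect_error(otsu_soa(random_image(2, n = 8, levels = 16), k = 15), "k")
})

test_that("SOA-Otsu hits the exhaustive optimum on bimodal images", {
  hits <- 0L
  for (s in 1:10) {
    img <- bimodal_image(s)
    ex <- otsu_exhaustive(img_histogram(img), 1)
    so <- otsu_soa(img, k = 1, params = soa_params(30, 100, seed = s))
    expect_lte(so$score, ex$score + 1e-9) # the oracle is the global optimum
    if (isTRUE(all.equal(so$score, ex$score))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("SOA-Otsu at k=2 comes within 1% of the exhaustive optimum", {
  ok <- 0L
  for (s in 1:10) {
    img <- trimodal_image(s)
    ex <- otsu_exhaustive(img_histogram(img), 2)
    so <- otsu_soa(img, k = 2, params = soa_params(30, 100, seed = s))
    expect_lte(so$score, ex$score + 1e-9)
    if (so$score >= 0.99 * ex$score) ok <- ok + 1L
  }
  expect_gte(ok, 8L)
})

test_that("SOA-Otsu on a constant image scores zero", {
  img <- gray_image(matrix(9L, 16, 16), levels = 64)
  so <- otsu_soa(img, k = 1, params = soa_params(10, 20, seed = 1))
  expect_equal(so$score, 0)
})

test_that("threshold application follows the boundary convention", {
  img <- gray_image(matrix(c(127L, 128L, 0L, 255L), 2, 2))
  lab <- apply_thresholds(img, 127)
  expect_equal(lab[1, 1], 0L) # 127 <= t -> label 0
  expect_equal(lab[2, 1], 1L) # 128 > t  -> label 1
  expect_equal(lab[1, 2], 0L)
  expect_equal(lab[2, 2], 1L)

  const <- gray_image(matrix(50L, 4, 4))
  expect_true(all(apply_thresholds(const, c(10, 100)) == 1L))
})

test_that("labels partition the image and label masses match class stats", {
  img <- random_image(seed = 12, n = 24)
  t <- c(60L, 170L)
  lab <- apply_thresholds(img, t)
  expect_true(all(lab %in% 0:2))
  st <- class_stats(img_histogram(img), t)
  for (n in 0:2) {
    expect_equal(mean(lab == n), st$omega[st$segment == n])
  }
})

test_that("total variance decomposes into within plus between at every threshold", {
  img <- random_image(seed = 21, n = 16, levels = 64)
  h <- img_histogram(img)
  for (t in 1:62) {
    vd <- variance_decomposition(h, t)
    expect_equal(vd$total, vd$within + vd$between, tolerance = 1e-9)
  }
})

test_that("criterion is unchanged by zero-probability levels", {
  p <- c(0.25, 0.25, 0.25, 0.25, 0, 0, 0, 0)
  expect_equal(
    between_class_variance(p, 1),
    between_class_variance(p, c(1)) # same thresholds, padded levels inert
  )
  p2 <- c(p, rep(0, 8))
  expect_equal(between_class_variance(p, 1), between_class_variance(p2, 1))
})

test_that("a bright lesion on dark background is segmented with high IoU", {
  size <- 64
  xs <- matrix(seq_len(size), size, size)
  ys <- t(xs)
  truth <- ((xs - 30)^2 / 144 + (ys - 36)^2 / 64) < 1
  img <- matrix(20L, size, size)
  img[truth] <- 220L
  set.seed(8)
  g <- add_gaussian_noise(gray_image(img), sd = 5)
  so <- otsu_soa(g, k = 1, params = soa_params(20, 50, seed = 8))
  mask <- lesion_mask(apply_thresholds(g, so$thresholds))
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.9)
})
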