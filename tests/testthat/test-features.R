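test_that("squash has the documented fixed points and asymptote", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  v <- c(1, 0, 0)
  expect_equal(sqrt(sum(squash(v)^2)), 0.5)
  expect_gt(sqrt(sum(squash(1e6 * v)^2)), 0.999999)
  expect_lt(sqrt(sum(squash(1e6 * v)^2)), 1)
})

test_that("squash preserves direction and is norm-monotone", {
  set.seed(1)
  v <- rnorm(5)
  sv <- squash(v)
  expect_equal(sv / sqrt(sum(sv^2)), v / sqrt(sum(v^2)))
  norms <- seq(0.1, 5, by = 0.1)
  out <- vapply(norms, function(r) sqrt(sum(squash(r * v / sqrt(sum(v^2)))^2)), numeric(1))
  expect_true(all(diff(out) > 0))
})

test_that("dynamic routing collapses to squash for a single pair", {
  pred <- array(c(3, 4), dim = c(1, 1, 2))
  r <- dynamic_routing(pred, iterations = 2)
  expect_equal(r$couplings[1, 1], 1)
  expect_equal(as.numeric(r$outputs), squash(c(3, 4)))
})

test_that("identical predictions give uniform couplings after one iteration", {
  pred <- array(0, dim = c(3, 4, 2))
  for (j in 1:4) pred[, j, ] <- matrix(c(1, 2), 3, 2, byrow = TRUE)
  r <- dynamic_routing(pred, iterations = 1)
  expect_equal(unname(r$couplings), matrix(0.25, 3, 4))
})

test_that("routing matches a step-by-step manual recomputation", {
  # 2 inputs x 2 outputs x 2 dims, hand-set votes, 3 iterations
  pred <- array(0, dim = c(2, 2, 2))
  pred[1, 1, ] <- c(1, 0)
  pred[1, 2, ] <- c(0, 1)
  pred[2, 1, ] <- c(0.5, 0.5)
  pred[2, 2, ] <- c(-0.5, 0.5)
  # independent unrolled recomputation (scalar arithmetic only)
  sq <- function(v) {
    n2 <- sum(v^2)
    if (n2 == 0) v else (n2 / (1 + n2)) * v / sqrt(n2)
  }
  b <- matrix(0, 2, 2)
  for (it in 1:3) {
    cpl <- t(apply(b, 1, function(row) exp(row) / sum(exp(row))))
    out <- matrix(0, 2, 2)
    for (j in 1:2) {
      s <- cpl[1, j] * pred[1, j, ] + cpl[2, j] * pred[2, j, ]
      out[j, ] <- sq(s)
    }
    for (i in 1:2) for (j in 1:2) b[i, j] <- b[i, j] + sum(pred[i, j, ] * out[j, ])
  }
  r <- dynamic_routing(pred, iterations = 3)
  expect_equal(r$outputs, out, tolerance = 1e-12)
  expect_equal(unname(r$couplings), unname(cpl), tolerance = 1e-12)
})

test_that("coupling coefficients sum to one at every routing iteration", {
  set.seed(5)
  pred <- array(rnorm(6 * 4 * 3), dim = c(6, 4, 3))
  r <- dynamic_routing(pred, iterations = 4)
  for (cpl in r$coupling_trace) {
    expect_equal(rowSums(cpl), rep(1, 6), tolerance = 1e-9)
  }
})

test_that("the capsule encoder produces the documented feature length", {
  img <- random_image(seed = 2, n = 64)
  f <- capsnet_encode(img)
  expect_length(f, 186L)
  expect_identical(capsnet_encode(img), f) # deterministic given the seed
  norms <- attr(f, "capsule_norms")
  expect_true(all(norms >= 0 & norms < 1))
})

test_that("capsule shape arithmetic validates 64 and 512 inputs and rejects misfits", {
  cfg <- caps_config()
  s64 <- caps_shape(cfg, 64, 64)
  expect_equal(s64$n, 186L)
  s512 <- caps_shape(cfg, 512, 512)
  expect_equal(s512$n, 186L)
  expect_gt(s512$n_primary, s64$n_primary)
  expect_error(caps_shape(cfg, 12, 12), "fit")
})

test_that("the bottleneck encoder produces a finite length-1000 vector", {
  img <- random_image(seed = 3, n = 64)
  f <- bottleneck_encode(img)
  expect_length(f, 1000L)
  expect_identical(bottleneck_encode(img), f)
  zeros <- gray_image(matrix(0L, 64, 64))
  fz <- bottleneck_encode(zeros)
  expect_true(all(is.finite(fz)))
})

test_that("a zero-compress residual block is the identity", {
  set.seed(9)
  x <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  w <- list(
    expand = matrix(rnorm(4 * 16), 4, 16),
    depthwise = array(rnorm(3 * 3 * 16), dim = c(3, 3, 16)),
    compress = matrix(0, 16, 4)
  )
  expect_equal(bottleneck_block(x, w, stride = 1L), x)
})

test_that("fusion concatenates verbatim and splits back exactly", {
  a <- rnorm(186)
  b <- rnorm(1000)
  f <- fuse_features(a, b)
  expect_length(f, 1186L)
  expect_equal(as.numeric(f)[1:186], a)
  expect_equal(as.numeric(f)[187:1186], b)
  sp <- split_fused(f)
  expect_equal(sp$a, a)
  expect_equal(sp$b, b)
  # empty first path is the identity on the second
  f0 <- fuse_features(numeric(0), b)
  expect_equal(as.numeric(f0), b)
})

test_that("feature entropy scores constants at zero and uniform columns at log2(bins)", {
  x <- cbind(rep(3, 64), rep(seq(0, 15), 4))
  H <- feature_entropy(x, bins = 16)
  expect_equal(H[1], 0)
  expect_equal(H[2], 4) # log2(16) bits
  expect_equal(entropy_select(x, keep = 1), 2L)
})

test_that("entropy selection matches a histogram-entropy oracle", {
  set.seed(5)
  x <- matrix(rnorm(50 * 10), 50, 10)
  x[, 4] <- 1 # constant column ranks last
  keep <- 6
  # independent recomputation
  ent <- numeric(10)
  for (j in 1:10) {
    col <- x[, j]
    if (diff(range(col)) == 0) {
      ent[j] <- 0
    } else {
      cuts <- seq(min(col), max(col), length.out = 17)
      cnt <- table(cut(col, cuts, include.lowest = TRUE))
      pr <- cnt[cnt > 0] / 50
      ent[j] <- -sum(pr * log2(pr))
    }
  }
  oracle <- order(-ent, 1:10)[1:keep]
  expect_equal(entropy_select(x, keep = keep, bins = 16), oracle)
  # the constant column is ranked last, so keeping 9 of 10 drops it
  expect_false(4L %in% entropy_select(x, keep = 9, bins = 16))
})

test_that("entropy selection is permutation-equivariant", {
  set.seed(6)
  x <- matrix(rnorm(40 * 8), 40, 8)
  perm <- sample(8)
  sel <- entropy_select(x, keep = 3)
  sel_p <- entropy_select(x[, perm], keep = 3)
  expect_equal(perm[sel_p], sel)
})

test_that("keep larger than the column count is rejected", {
  expect_error(entropy_select(matrix(rnorm(20), 5, 4), keep = 5), "keep")
})
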