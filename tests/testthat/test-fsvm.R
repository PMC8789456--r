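test_that("centroid-linear memberships behave at the centroid and the farthest point", {
  x <- rbind(c(0, 0), c(0, 0), c(4, 0), c(10, 10), c(10, 14))
  y <- c(1, 1, 1, -1, -1)
  s <- assign_memberships(x, y, sigma = 0.05)
  # first two points straddle the positive centroid at (4/3, 0)
  pos_centroid <- c(4 / 3, 0)
  d <- sqrt(colSums((t(x[1:3, ]) - pos_centroid)^2))
  expect_equal(which.max(s[1:3]), which.min(d))
  # farthest point in a class sits at (approximately) the floor
  expect_lt(s[which.max(d)], 0.06)
  # a point exactly at its class centroid gets membership 1
  x2 <- rbind(c(0, 0), c(-2, 0), c(2, 0), c(9, 9), c(11, 11))
  s2 <- assign_memberships(x2, c(1, 1, 1, -1, -1))
  expect_equal(s2[1], 1)
  expect_true(all(assign_memberships(x, y, scheme = "uniform") == 1))
})

test_that("a symmetric separable pair yields the textbook solution", {
  x <- rbind(c(-1, 0), c(1, 0))
  y <- c(-1, 1)
  m <- fsvm(x, y, C = 1000, kernel = "linear", memberships = c(1, 1))
  expect_equal(sort(m$sv), c(1L, 2L))
  expect_equal(m$alpha[1], m$alpha[2], tolerance = 1e-8)
  expect_equal(m$b, 0, tolerance = 1e-8)
  # decision boundary x1 = 0; the midpoint scores 0 and gets +1 by convention
  p <- predict(m, c(0, 0))
  expect_equal(p$decision, 0, tolerance = 1e-8)
  expect_equal(p$label, 1)
  # training points of a separable set are classified correctly
  expect_equal(predict(m, x)$label, y)
})

test_that("uniform memberships recover the standard C-SVM dual", {
  skip_if_not_installed("e1071")
  for (s in 1:6) {
    fx <- svm_fixture(s)
    m <- fsvm(fx$x, fx$y, C = 2, kernel = "rbf", gamma = 1,
              memberships = rep(1, 20), tol = 1e-10)
    sv <- e1071::svm(fx$x, factor(fx$y), scale = FALSE, kernel = "radial",
                     gamma = 1, cost = 2, tolerance = 1e-12)
    a_or <- numeric(20)
    a_or[sv$index] <- abs(sv$coefs)
    expect_lt(max(abs(a_or - m$alpha)), 1e-6)
  }
})

test_that("decision values agree with the reference solver on random test points", {
  skip_if_not_installed("e1071")
  fx <- svm_fixture(3)
  m <- fsvm(fx$x, fx$y, C = 2, kernel = "rbf", gamma = 1,
            memberships = rep(1, 20), tol = 1e-10)
  sv <- e1071::svm(fx$x, factor(fx$y), scale = FALSE, kernel = "radial",
                   gamma = 1, cost = 2, tolerance = 1e-12)
  set.seed(99)
  xt <- matrix(rnorm(200), 100, 2)
  dv <- attr(predict(sv, xt, decision.values = TRUE), "decision.values")
  sgn <- if (colnames(dv) == "1/-1") 1 else -1
  expect_lt(max(abs(predict(m, xt)$decision - sgn * dv[, 1])), 1e-5)
})

test_that("a low membership caps the outlier's dual coefficient", {
  set.seed(4)
  n <- 21
  x <- rbind(matrix(rnorm(20, sd = 0.5), 10, 2) + 2,
             matrix(rnorm(20, sd = 0.5), 10, 2) - 2,
             c(-2, -2)) # outlier labelled +1 deep in the -1 region
  y <- c(rep(1, 10), rep(-1, 10), 1)
  s <- rep(1, n)
  s[n] <- 0.05
  m_fuzzy <- fsvm(x, y, C = 10, kernel = "rbf", gamma = 0.5, memberships = s)
  m_plain <- fsvm(x, y, C = 10, kernel = "rbf", gamma = 0.5, memberships = rep(1, n))
  expect_lte(m_fuzzy$alpha[n], 0.5 + 1e-8) # s_i * C
  expect_gt(m_plain$alpha[n], 0.5)         # unconstrained up to C = 10
})

test_that("trained models satisfy dual feasibility", {
  for (s in c(2, 5)) {
    fx <- svm_fixture(s)
    mem <- assign_memberships(fx$x, fx$y)
    m <- fsvm(fx$x, fx$y, C = 3, kernel = "rbf", gamma = 0.8, memberships = mem)
    expect_lt(abs(sum(m$alpha * m$y)), 1e-7)
    expect_true(all(m$alpha >= -1e-8))
    expect_true(all(m$alpha <= mem * 3 + 1e-8))
  }
})

test_that("lowering a membership never raises that sample's alpha cap, and a capped sample's violation grows", {
  fx <- svm_fixture(7)
  mem <- rep(1, 20)
  m1 <- fsvm(fx$x, fx$y, C = 2, kernel = "rbf", gamma = 1, memberships = mem)
  i <- which.max(m1$alpha)
  mem2 <- mem
  mem2[i] <- 0.2
  m2 <- fsvm(fx$x, fx$y, C = 2, kernel = "rbf", gamma = 1, memberships = mem2)
  expect_lte(m2$alpha[i], 0.2 * 2 + 1e-8)
  if (m1$alpha[i] >= 2 - 1e-6) {
    # at the cap in both fits: the margin violation weakly increases
    v1 <- 1 - fx$y[i] * predict(m1, fx$x[i, ])$decision
    v2 <- 1 - fx$y[i] * predict(m2, fx$x[i, ])$decision
    expect_gte(v2, v1 - 1e-6)
  }
})

test_that("duplicating all points leaves the linear decision boundary unchanged", {
  # with a margin-interior (no coefficient at its cap) solution, the
  # duplicated problem shares the same unique primal optimum
  set.seed(9)
  n <- 20
  x <- matrix(rnorm(n * 2), n, 2)
  y <- rep(c(1, -1), each = 10)
  x[y == 1, ] <- x[y == 1, ] + 6
  m1 <- fsvm(x, y, C = 5, kernel = "linear", memberships = rep(1, n))
  m2 <- fsvm(rbind(x, x), c(y, y), C = 5, kernel = "linear",
             memberships = rep(1, 2 * n))
  set.seed(31)
  xt <- matrix(rnorm(40), 20, 2) + 3
  expect_equal(predict(m1, xt)$label, predict(m2, xt)$label)
  expect_lt(max(abs(predict(m2, xt)$decision - predict(m1, xt)$decision)), 1e-5)
})

test_that("one-vs-rest separates three well-separated blobs perfectly", {
  blobs <- linearly_separable_features(30, dims = 2, separation = 10, seed = 0, classes = 3)
  m <- fsvm_multiclass(blobs$x, blobs$labels, C = 10, kernel = "rbf")
  pred <- predict(m, blobs$x)
  expect_equal(mean(pred$label == as.character(blobs$labels)), 1)
})

test_that("two-class one-vs-rest agrees with the single binary model", {
  fx <- svm_fixture(11)
  lab <- ifelse(fx$y > 0, "pos", "neg")
  ens <- fsvm_multiclass(fx$x, lab, C = 2, kernel = "rbf", gamma = 1,
                         scheme = "uniform", levels = c("pos", "neg"))
  bin <- fsvm(fx$x, fx$y, C = 2, kernel = "rbf", gamma = 1, memberships = rep(1, 20))
  set.seed(17)
  xt <- matrix(rnorm(60), 30, 2)
  pe <- predict(ens, xt)$label
  pb <- ifelse(predict(bin, xt)$label > 0, "pos", "neg")
  expect_equal(pe, pb)
})

test_that("class order only matters on exact ties", {
  blobs <- linearly_separable_features(15, dims = 2, separation = 8, seed = 2, classes = 3)
  lv <- levels(blobs$labels)
  m1 <- fsvm_multiclass(blobs$x, blobs$labels, C = 5, levels = lv)
  m2 <- fsvm_multiclass(blobs$x, blobs$labels, C = 5, levels = rev(lv))
  set.seed(23)
  xt <- matrix(rnorm(40), 20, 2) + 2
  p1 <- predict(m1, xt)
  p2 <- predict(m2, xt)
  dec1 <- as.matrix(p1[, paste0("decision_", lv)])
  ties <- apply(dec1, 1, function(r) sum(abs(r - max(r)) < 1e-12) > 1)
  expect_equal(p1$label[!ties], p2$label[!ties])
})

test_that("invalid training input is rejected", {
  expect_error(fsvm(matrix(1:4, 2, 2), c(1, 1)), "classes")
  expect_error(fsvm(matrix(1:4, 2, 2), c(0, 1)), "-1")
  expect_error(fsvm(matrix(1:4, 2, 2), c(-1, 1), C = -1), "positive")
})
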