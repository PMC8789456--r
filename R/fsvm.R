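#' Fuzzy membership assignment
#'
#' In the fuzzy SVM every training point carries a membership
#' `s_i in [sigma, 1]` that scales its slack penalty, so outliers influence
#' the decision surface less. The default `"centroid-linear"` scheme sets
#' `s_i = 1 - d_i / (d_max + delta)` from the distance `d_i` of the point
#' to its class centroid (`d_max` the largest such distance in the class,
#' `delta = 1e-6 * d_max`), clamped to `[sigma, 1]`. The `"uniform"` scheme
#' assigns `s_i = 1` to every point, recovering the standard C-SVM.
#'
#' @param x numeric feature matrix, samples in rows.
#' @param y labels in `{-1, +1}` (binary) or any label vector; centroids
#'   are computed per distinct label.
#' @param scheme `"centroid-linear"` or `"uniform"`.
#' @param sigma membership floor `sigma > 0` (default 0.05).
#' @return Numeric membership vector in `[sigma, 1]`.
#' @export
assign_memberships <- function(x, y, scheme = c("centroid-linear", "uniform"),
                               sigma = 0.05) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  if (length(y) != nrow(x)) stop("`x` and `y` lengths disagree", call. = FALSE)
  if (sigma <= 0 || sigma > 1) stop("`sigma` must lie in (0, 1]", call. = FALSE)
  if (scheme == "uniform") return(rep(1, nrow(x)))
  s <- numeric(nrow(x))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) == 0L) stop("empty class", call. = FALSE)
    centroid <- colMeans(x[idx, , drop = FALSE])
    d <- sqrt(rowSums(sweep(x[idx, , drop = FALSE], 2L, centroid)^2))
    dmax <- max(d)
    s[idx] <- if (dmax == 0) 1 else 1 - d / (dmax + 1e-6 * dmax)
  }
  pmin(pmax(s, sigma), 1)
}

kernel_spec <- function(kernel, gamma, degree, coef0) {
  list(kernel = kernel, gamma = gamma, degree = degree, coef0 = coef0)
}

kernel_matrix <- function(ks, x, z = NULL) {
  x <- as.matrix(x)
  z <- if (is.null(z)) x else as.matrix(z)
  switch(ks$kernel,
    linear = x %*% t(z),
    polynomial = (x %*% t(z) + ks$coef0)^ks$degree,
    rbf = {
      xn <- rowSums(x^2)
      zn <- rowSums(z^2)
      d2 <- outer(xn, zn, `+`) - 2 * x %*% t(z)
      exp(-ks$gamma * pmax(d2, 0))
    },
    stop("unknown kernel", call. = FALSE)
  )
}

default_gamma <- function(x) {
  v <- stats::var(as.numeric(x))
  if (!is.finite(v) || v == 0) v <- 1
  1 / (ncol(x) * v)
}

# SMO solver for the fuzzy-SVM dual
#   max_alpha  sum alpha_i - 1/2 sum_ij alpha_i alpha_j y_i y_j K_ij
#   s.t.       sum y_i alpha_i = 0,  0 <= alpha_i <= s_i * C
# The per-sample upper bound s_i * C is the only difference from the
# standard C-SVM dual. Working pairs are chosen as the maximal violating
# pair; termination when the KKT gap m(alpha) - M(alpha) < tol.
smo_solve <- function(K, y, C_i, tol = 1e-8, max_passes = NULL) {
  n <- length(y)
  if (is.null(max_passes)) max_passes <- max(200L * n, 20000L)
  alpha <- numeric(n)
  f <- numeric(n) # f_i = sum_j alpha_j y_j K_ij (no bias)
  it <- 0L
  repeat {
    it <- it + 1L
    grad <- y - f # equals -y_i * dual-gradient_i
    up <- (y > 0 & alpha < C_i - 1e-15) | (y < 0 & alpha > 1e-15)
    low <- (y < 0 & alpha < C_i - 1e-15) | (y > 0 & alpha > 1e-15)
    if (!any(up) || !any(low)) break
    m_up <- max(grad[up])
    m_low <- min(grad[low])
    if (m_up - m_low < tol || it > max_passes) break
    i <- which(up)[which.max(grad[up])]
    j <- which(low)[which.min(grad[low])]
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta < 1e-12) eta <- 1e-12
    s <- y[i] * y[j]
    aj_old <- alpha[j]
    ai_old <- alpha[i]
    if (s < 0) {
      L <- max(0, aj_old - ai_old)
      H <- min(C_i[j], C_i[i] + aj_old - ai_old)
    } else {
      L <- max(0, ai_old + aj_old - C_i[i])
      H <- min(C_i[j], ai_old + aj_old)
    }
    if (H - L < 1e-15) next
    Ei <- f[i] - y[i]
    Ej <- f[j] - y[j]
    aj <- aj_old + y[j] * (Ei - Ej) / eta
    aj <- min(max(aj, L), H)
    ai <- ai_old + s * (aj_old - aj)
    if (abs(aj - aj_old) < 1e-15) next
    alpha[i] <- ai
    alpha[j] <- aj
    f <- f + (ai - ai_old) * y[i] * K[, i] + (aj - aj_old) * y[j] * K[, j]
  }
  list(alpha = alpha, f = f, iterations = it, gap = {
    grad <- y - f
    up <- (y > 0 & alpha < C_i - 1e-15) | (y < 0 & alpha > 1e-15)
    low <- (y < 0 & alpha < C_i - 1e-15) | (y > 0 & alpha > 1e-15)
    if (any(up) && any(low)) max(grad[up]) - min(grad[low]) else 0
  })
}

#' Train a fuzzy support vector machine
#'
#' Solves the weighted-slack soft-margin problem through its dual, where
#' each dual coefficient is capped at `s_i * C` by the sample's fuzzy
#' membership. The bias `b` is recovered by averaging `y_i - f(x_i)` over
#' free support vectors (`0 < alpha_i < s_i C`); if none are free a
#' midpoint rule on the KKT bounds is used (with a warning).
#'
#' @param x numeric feature matrix, samples in rows.
#' @param y labels in `{-1, +1}` (numeric) with both classes present.
#' @param C slack trade-off, `C > 0`.
#' @param kernel `"rbf"` (default), `"linear"`, or `"polynomial"`.
#' @param gamma RBF width; default `1 / (ncol(x) * var(x))`.
#' @param degree,coef0 polynomial kernel parameters.
#' @param memberships optional membership vector; computed with
#'   [assign_memberships()] when `NULL`.
#' @param scheme,sigma passed to [assign_memberships()].
#' @param tol KKT tolerance of the dual solver (default 1e-8).
#' @return An object of class `fsvm` with dual coefficients `alpha`, bias
#'   `b`, support-vector indices, the kernel spec, and memberships.
#' @export
fsvm <- function(x, y, C = 1, kernel = c("rbf", "linear", "polynomial"),
                 gamma = NULL, degree = 3, coef0 = 1,
                 memberships = NULL, scheme = "centroid-linear",
                 sigma = 0.05, tol = 1e-8) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("`y` must contain only -1 and +1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (C <= 0) stop("`C` must be positive", call. = FALSE)
  if (is.null(gamma)) gamma <- default_gamma(x)
  if (is.null(memberships)) {
    memberships <- assign_memberships(x, y, scheme = scheme, sigma = sigma)
  }
  if (length(memberships) != nrow(x) || any(memberships <= 0) || any(memberships > 1)) {
    stop("`memberships` must lie in (0, 1] with one value per sample", call. = FALSE)
  }
  ks <- kernel_spec(kernel, gamma, degree, coef0)
  K <- kernel_matrix(ks, x)
  if (any(!is.finite(K))) stop("kernel matrix contains non-finite values", call. = FALSE)
  C_i <- memberships * C
  sol <- smo_solve(K, y, C_i, tol = tol)
  alpha <- sol$alpha
  sv <- which(alpha > tol)
  free <- which(alpha > tol & alpha < C_i - tol)
  if (length(free) > 0L) {
    b <- mean(y[free] - sol$f[free])
  } else {
    grad <- y - sol$f
    up <- (y > 0 & alpha < C_i - 1e-15) | (y < 0 & alpha > 1e-15)
    low <- (y < 0 & alpha < C_i - 1e-15) | (y > 0 & alpha > 1e-15)
    hi <- if (any(up)) max(grad[up]) else max(grad)
    lo <- if (any(low)) min(grad[low]) else min(grad)
    b <- (hi + lo) / 2
    warning("no free support vectors; bias set by the KKT midpoint rule", call. = FALSE)
  }
  structure(
    list(
      alpha = alpha, b = b, sv = sv, x = x, y = y,
      memberships = memberships, scheme = scheme, C = C,
      kernel = ks, tol = tol, solver = list(iterations = sol$iterations, gap = sol$gap)
    ),
    class = "fsvm"
  )
}

#' Predict with a fuzzy SVM
#'
#' Decision value `f(x) = sum_i alpha_i y_i K(x_i, x) + b`; the label is
#' `sign(f(x))` with `sign(0)` mapped to `+1`.
#'
#' @param object an [fsvm()] model.
#' @param newdata feature matrix (or single row vector).
#' @param ... unused.
#' @return A tibble with columns `label` (-1/+1) and `decision`.
#' @export
predict.fsvm <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  dec <- fsvm_decision(object, newdata)
  tibble::tibble(label = ifelse(dec >= 0, 1, -1), decision = dec)
}

fsvm_decision <- function(object, newdata) {
  act <- object$sv
  if (length(act) == 0L) return(rep(object$b, nrow(newdata)))
  Kx <- kernel_matrix(object$kernel, newdata, object$x[act, , drop = FALSE])
  as.numeric(Kx %*% (object$alpha[act] * object$y[act]) + object$b)
}

#' @export
print.fsvm <- function(x, ...) {
  cat(sprintf(
    "<fsvm> %s kernel, C = %g, %d support vectors (%d samples), b = %.4g\n",
    x$kernel$kernel, x$C, length(x$sv), length(x$y), x$b
  ))
  invisible(x)
}

#' Support-vector summary of a fuzzy SVM
#'
#' @param x an [fsvm()] model.
#' @param ... unused.
#' @return A tibble with one row per support vector: `index`, `alpha`,
#'   `y`, `membership`, and the cap `alpha_max = membership * C`.
#' @export
tidy.fsvm <- function(x, ...) {
  tibble::tibble(
    index = x$sv,
    alpha = x$alpha[x$sv],
    y = x$y[x$sv],
    membership = x$memberships[x$sv],
    alpha_max = x$memberships[x$sv] * x$C
  )
}

#' @rdname tidy.fsvm
#' @export
glance.fsvm <- function(x, ...) {
  tibble::tibble(
    kernel = x$kernel$kernel, C = x$C, n = length(x$y),
    n_sv = length(x$sv), b = x$b,
    equality_residual = sum(x$alpha * x$y),
    kkt_gap = x$solver$gap
  )
}

#' One-vs-rest multiclass fuzzy SVM
#'
#' Trains one binary [fsvm()] per class (that class `+1`, the rest `-1`),
#' recomputing memberships for each binary problem. Prediction takes the
#' class with the largest decision value; exact ties go to the earlier
#' class in `levels`.
#'
#' @inheritParams fsvm
#' @param labels class labels (factor or character/atomic vector).
#' @param levels optional explicit class order.
#' @return An object of class `fsvm_ovr`.
#' @export
fsvm_multiclass <- function(x, labels, C = 1, kernel = "rbf", gamma = NULL,
                            degree = 3, coef0 = 1, scheme = "centroid-linear",
                            sigma = 0.05, tol = 1e-8, levels = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (is.null(levels)) levels <- unique(labels)
  if (length(levels) < 2L) stop("need at least two classes", call. = FALSE)
  if (is.null(gamma)) gamma <- default_gamma(x)
  models <- lapply(levels, function(cl) {
    yb <- ifelse(labels == cl, 1, -1)
    if (sum(yb > 0) < 2L) {
      warning(sprintf("class '%s' has fewer than 2 samples", cl), call. = FALSE)
    }
    fsvm(x, yb, C = C, kernel = kernel, gamma = gamma, degree = degree,
         coef0 = coef0, scheme = scheme, sigma = sigma, tol = tol)
  })
  names(models) <- levels
  structure(list(models = models, levels = levels), class = "fsvm_ovr")
}

#' @export
print.fsvm_ovr <- function(x, ...) {
  cat(sprintf("<fsvm_ovr> one-vs-rest ensemble over %d classes: %s\n",
              length(x$levels), paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict with a one-vs-rest fuzzy SVM ensemble
#'
#' @param object an [fsvm_multiclass()] ensemble.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return A tibble with the predicted `label` and one decision column per
#'   class (`decision_<class>`).
#' @export
predict.fsvm_ovr <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  dec <- vapply(object$models, fsvm_decision, numeric(nrow(newdata)),
                newdata = newdata)
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1L)
  pick <- apply(dec, 1L, which.max) # which.max breaks ties by class order
  out <- tibble::tibble(label = object$levels[pick])
  dcols <- tibble::as_tibble(as.data.frame(dec))
  names(dcols) <- paste0("decision_", object$levels)
  dplyr::bind_cols(out, dcols)
}
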