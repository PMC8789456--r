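#' Synthetic CT-slice configuration
#'
#' The generator emulates axial brain-CT slices at desk scale: an
#' elliptical skull ring around brain tissue with a smooth intensity
#' field, plus one class-dependent hyperdense lesion per slice. The
#' default class counts mirror the benchmark collection the pipeline
#' targets (IVT 24, IPC 72, SAD 18, EPI 171, SBD 56; 341 slices), scalable
#' by `scale`. Lesion geometries are cartoon proxies of the radiological
#' appearance, not anatomical simulation:
#'
#' * `EPI` — biconvex lens pressed against the inner skull margin;
#' * `SBD` — thin crescent hugging the skull;
#' * `IPC` — compact round blob in the parenchyma;
#' * `IVT` — small blob in the ventricle region near the slice centre;
#' * `SAD` — two thin curvilinear streaks at mid radius.
#'
#' Intensities (8-bit): background 85, tissue ~95 with a smooth +-5
#' field, skull ring 112, lesion uniform in `[230, 250]` per slice — the
#' lesion is always the brightest structure (as on a skull-suppressed
#' slice), so single-threshold Otsu isolates it exactly in the noise-free
#' limit. Gaussian noise is added first, then salt-and-pepper noise
#' corrupting exactly `round(rate * pixels)` pixels.
#'
#' @param size square image side (default 64; 512 supported).
#' @param counts named per-class slice counts.
#' @param scale multiplies all counts (result rounded up to >= 1).
#' @param lesion_intensity 2-vector, per-slice lesion intensity range.
#' @param background,tissue,skull base intensities.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param salt_pepper impulse noise rate in `[0, 0.5)`.
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @return A config list for [generate_ich_dataset()].
#' @export
synthetic_config <- function(size = 64L,
                             counts = c(IVT = 24L, IPC = 72L, SAD = 18L, EPI = 171L, SBD = 56L),
                             scale = 1,
                             lesion_intensity = c(230L, 250L),
                             background = 85L, tissue = 95L, skull = 112L,
                             noise_sd = 3, salt_pepper = 0.02,
                             seed = 0L) {
  size <- as.integer(size)
  if (size < 32L) stop("`size` must be >= 32 for the lesions to fit", call. = FALSE)
  if (salt_pepper < 0 || salt_pepper >= 0.5) {
    stop("`salt_pepper` must lie in [0, 0.5)", call. = FALSE)
  }
  nm <- names(counts) %||% ich_classes[seq_along(counts)]
  counts <- pmax(1L, as.integer(ceiling(counts * scale)))
  names(counts) <- nm
  list(
    size = size, counts = counts, lesion_intensity = lesion_intensity,
    background = background, tissue = tissue, skull = skull,
    noise_sd = noise_sd, salt_pepper = salt_pepper, seed = as.integer(seed)
  )
}

# Squared normalized elliptical radius of every pixel: < 1 inside the
# inner skull table, ~1 at the inner boundary.
skull_geometry <- function(size) {
  cx <- (size + 1) / 2
  a <- 0.44 * size
  b <- 0.38 * size
  xs <- matrix(seq_len(size), size, size)            # row coordinate
  ys <- matrix(seq_len(size), size, size, byrow = TRUE)
  e2 <- ((xs - cx) / b)^2 + ((ys - cx) / a)^2
  list(e = sqrt(e2), cx = cx, a = a, b = b, xs = xs, ys = ys)
}

# One lesion mask for a class; geometry randomized from the current RNG.
lesion_geometry <- function(class, geo, size) {
  cx <- geo$cx
  inner <- geo$e < 0.985
  phi <- stats::runif(1, 0, 2 * pi)
  # point on the inner skull margin and its inward unit normal
  px <- cx + 0.95 * geo$b * cos(phi)
  py <- cx + 0.95 * geo$a * sin(phi)
  mask <- switch(class,
    EPI = {
      nrm <- sqrt((cx - px)^2 + (cx - py)^2)
      nx <- (cx - px) / nrm
      ny <- (cx - py) / nrm
      R <- 0.30 * size
      w <- stats::runif(1, 0.11, 0.15) * size
      D <- R - w / 2
      c1x <- px + D * nx
      c1y <- py + D * ny
      c2x <- px - D * nx
      c2y <- py - D * ny
      lens <- ((geo$xs - c1x)^2 + (geo$ys - c1y)^2 < R^2) &
        ((geo$xs - c2x)^2 + (geo$ys - c2y)^2 < R^2)
      lens & inner
    },
    SBD = {
      half <- stats::runif(1, 0.7, 0.9)
      ang <- atan2(geo$ys - cx, geo$xs - cx)
      dang <- abs(((ang - phi + pi) %% (2 * pi)) - pi)
      geo$e >= 0.90 & geo$e <= 0.985 & dang < half
    },
    IPC = {
      r <- stats::runif(1, 0.075, 0.10) * size
      d <- stats::runif(1, 0.15, 0.40)
      bx <- cx + d * geo$b * cos(phi)
      by <- cx + d * geo$a * sin(phi)
      (geo$xs - bx)^2 + (geo$ys - by)^2 < r^2
    },
    IVT = {
      r <- stats::runif(1, 0.040, 0.055) * size
      d <- stats::runif(1, 0, 0.12)
      bx <- cx + d * size * cos(phi)
      by <- cx + d * size * sin(phi)
      (geo$xs - bx)^2 + (geo$ys - by)^2 < r^2
    },
    SAD = {
      ang <- atan2(geo$ys - cx, geo$xs - cx)
      m <- matrix(FALSE, size, size)
      for (s in 1:2) {
        phis <- stats::runif(1, 0, 2 * pi)
        span <- stats::runif(1, 0.30, 0.40)
        rad <- stats::runif(1, 0.55, 0.68)
        dang <- abs(((ang - phis + pi) %% (2 * pi)) - pi)
        m <- m | (geo$e >= rad - 0.03 & geo$e <= rad + 0.03 & dang < span)
      }
      m
    },
    stop(sprintf("unknown class '%s'", class), call. = FALSE)
  )
  mask
}

#' Add Gaussian intensity noise to an image
#'
#' @param image a [gray_image()] or matrix.
#' @param sd noise standard deviation in intensity units.
#' @return A [gray_image()] (values rounded and clamped to the level range).
#' @export
add_gaussian_noise <- function(image, sd) {
  image <- as_gray_image(image)
  L <- gray_levels(image)
  v <- unclass(image) + stats::rnorm(length(image), sd = sd)
  gray_image(matrix(pmin(pmax(round(v), 0), L - 1L), nrow(image), ncol(image)), levels = L)
}

#' Add salt-and-pepper noise to an image
#'
#' Corrupts exactly `round(rate * length(image))` distinct pixels, each set
#' to 0 or `L - 1` with equal probability.
#'
#' @inheritParams add_gaussian_noise
#' @param rate corruption rate in `[0, 0.5)`.
#' @return A [gray_image()].
#' @export
add_salt_pepper <- function(image, rate) {
  image <- as_gray_image(image)
  L <- gray_levels(image)
  n <- round(rate * length(image))
  if (n == 0) return(image)
  px <- unclass(image)
  idx <- sample.int(length(px), n)
  px[idx] <- ifelse(stats::runif(n) < 0.5, 0L, L - 1L)
  gray_image(px, levels = L)
}

#' Generate a labeled synthetic CT-slice dataset
#'
#' @param cfg a [synthetic_config()].
#' @return A tibble with columns `id`, `label` (factor in the order of
#'   `cfg$counts`), `image` (list of [gray_image()]), and `mask` (list of
#'   logical ground-truth lesion masks). Deterministic given `cfg$seed`.
#' @export
generate_ich_dataset <- function(cfg = synthetic_config()) {
  with_opt_seed(cfg$seed, {
    geo <- skull_geometry(cfg$size)
    base_classes <- names(cfg$counts)
    rows <- list()
    id <- 0L
    for (cl in base_classes) {
      for (rep_i in seq_len(cfg$counts[[cl]])) {
        id <- id + 1L
        smooth <- tissue_field(cfg$size)
        img <- matrix(cfg$background, cfg$size, cfg$size)
        inside <- geo$e < 1
        ring <- geo$e >= 1 & geo$e < 1.12
        img[inside] <- pmin(pmax(cfg$tissue + smooth[inside], cfg$background + 3), cfg$skull - 4)
        img[ring] <- cfg$skull
        mask <- lesion_geometry(cl, geo, cfg$size)
        if (!any(mask)) stop(sprintf("lesion for class %s does not fit at size %d", cl, cfg$size),
                             call. = FALSE)
        lesion_val <- round(stats::runif(1, cfg$lesion_intensity[1], cfg$lesion_intensity[2]))
        img[mask] <- lesion_val
        g <- gray_image(round(img), levels = 256L)
        if (cfg$noise_sd > 0) g <- add_gaussian_noise(g, cfg$noise_sd)
        if (cfg$salt_pepper > 0) g <- add_salt_pepper(g, cfg$salt_pepper)
        rows[[id]] <- tibble::tibble(
          id = id, label = cl, image = list(g), mask = list(mask)
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    out$label <- factor(out$label, levels = base_classes)
    out
  })
}

# Smooth low-frequency intensity variation over the tissue.
tissue_field <- function(size) {
  fx <- stats::runif(2, 0.5, 1.5)
  ph <- stats::runif(2, 0, 2 * pi)
  amp <- stats::runif(1, 2, 5)
  xs <- matrix(seq_len(size) / size, size, size)
  ys <- matrix(seq_len(size) / size, size, size, byrow = TRUE)
  amp * (cos(2 * pi * fx[1] * xs + ph[1]) + cos(2 * pi * fx[2] * ys + ph[2])) / 2
}

#' Shape descriptors of a lesion mask
#'
#' Four simple descriptors that separate the five synthetic lesion
#' geometries: pixel `area`; `eccentricity` and `elongation` from the
#' eigenvalues of the pixel-coordinate covariance; and `boundary_contact`,
#' the fraction of lesion pixels lying near the inner skull table
#' (normalized elliptical radius > 0.82).
#'
#' @param mask logical lesion mask.
#' @return A one-row tibble.
#' @export
shape_descriptors <- function(mask) {
  size <- nrow(mask)
  geo <- skull_geometry(size)
  idx <- which(mask, arr.ind = TRUE)
  area <- nrow(idx)
  if (area == 0L) stop("mask is empty", call. = FALSE)
  if (area > 1L) {
    cv <- stats::cov(idx)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 1e-9)
    ecc <- sqrt(1 - ev[2] / ev[1])
    elong <- sqrt(ev[1] / ev[2])
  } else {
    ecc <- 0
    elong <- 1
  }
  contact <- mean(geo$e[mask] > 0.82)
  tibble::tibble(
    area = area, eccentricity = ecc,
    boundary_contact = contact, elongation = elong
  )
}

#' Gaussian-blob feature fixture for classifier tests
#'
#' Draws `n_per_class` points per class from unit-variance Gaussians whose
#' centres are `separation` apart (separation therefore measured in sigma
#' units). With `separation = 0` all classes coincide.
#'
#' @param n_per_class points per class.
#' @param dims feature dimension.
#' @param separation minimum centre-to-centre distance in sigma units.
#' @param seed integer seed.
#' @param classes number of classes (default 2).
#' @return A list with `x` (matrix) and `labels` (factor).
#' @export
linearly_separable_features <- function(n_per_class, dims = 2L, separation = 5,
                                        seed = 0L, classes = 2L) {
  if (separation < 0) stop("`separation` must be >= 0", call. = FALSE)
  with_opt_seed(seed, {
    centers <- matrix(stats::rnorm(classes * dims), classes, dims)
    if (separation > 0 && classes > 1L) {
      dmin <- min(stats::dist(centers))
      if (dmin == 0) dmin <- 1
      centers <- centers * (separation / dmin)
    } else {
      centers[] <- 0
    }
    x <- do.call(rbind, lapply(seq_len(classes), function(k) {
      matrix(stats::rnorm(n_per_class * dims), n_per_class, dims) +
        matrix(centers[k, ], n_per_class, dims, byrow = TRUE)
    }))
    labels <- factor(rep(paste0("c", seq_len(classes)), each = n_per_class))
    list(x = x, labels = labels)
  })
}
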